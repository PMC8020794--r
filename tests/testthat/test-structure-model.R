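test_that("unit cell orthogonalization round-trips and volume is right", {
  uc <- unit_cell(28.3, 31.1, 40.2, 83, 97, 112)
  expect_gt(uc$volume, 0)
  set.seed(1)
  pts <- matrix(runif(30, -10, 40), ncol = 3)
  back <- frac2orth(uc, orth2frac(uc, pts))
  expect_lt(max(abs(back - pts)), 1e-6)
  # cubic special case
  expect_equal(unit_cell(10, 10, 10)$volume, 1000)
})

test_that("model PDB write/read round-trips coordinates and metadata", {
  toy <- build_toy_system(seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model(toy$dark, path)
  back <- read_model(path)
  expect_equal(nrow(back$atoms), nrow(toy$dark$atoms))
  expect_lt(max(abs(atom_xyz(back) - atom_xyz(toy$dark))), 1e-3)
  expect_equal(back$cell$a, toy$dark$cell$a, tolerance = 1e-6)
  expect_setequal(unique(back$atoms$element),
                  unique(toy$dark$atoms$element))
})

test_that("read_model requires a unit cell and reports parse failures", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00 10.00           C",
    "END"), path)
  expect_error(read_model(path), "cell")
  ok <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 10.00           C",
    "END"), ok)
  m <- read_model(ok)
  expect_equal(nrow(m$atoms), 1)
  expect_error(read_model("/nonexistent/file.pdb"), "not found")
})

test_that("mmCIF models are read with cell and elements populated", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_mini",
    "_cell.length_a    20.000", "_cell.length_b    20.000",
    "_cell.length_c    20.000", "_cell.angle_alpha 90.00",
    "_cell.angle_beta  90.00", "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M 'P 1'",
    "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
      "label_atom_id", "label_alt_id", "label_comp_id", "label_asym_id",
      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
      "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
      "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")),
    "ATOM 1 C CA . GLY A 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 1 GLY A CA 1",
    "ATOM 2 N N  . GLY A 1 1 ? 2.500 2.000 3.000 1.00 12.00 ? 1 GLY A N  1"),
    path)
  m <- read_model(path)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$cell$a, 20)
  expect_setequal(m$atoms$element, c("C", "N"))
  expect_equal(atom_distance(m, "name CA", "name N"), 1.5)
})

test_that("selectors are deterministic, order-stable, and validated", {
  toy <- build_toy_system(seed = 1)
  m <- toy$dark
  quad <- select_atoms(m, "resname RLY and name C12,C13,C14,C15")
  expect_length(quad, 4)
  expect_identical(quad, sort(quad))
  expect_gte(length(select_atoms(m, "element CL")), 1)
  expect_length(select_atoms(m, "resname XYZ"), 0)
  expect_length(select_atoms(m, "water"), 10)
  expect_length(select_atoms(m, "chain A and resi 2-4 and name CA"), 3)
  expect_error(select_atoms(m, "frobnicate Q"), "invalid selector")
})

test_that("highest-occupancy altloc is selected unless addressed", {
  atoms <- data.frame(
    chain = "A", resno = 1L, resname = "SER",
    atom = c("OG", "OG", "CB"), element = c("O", "O", "C"),
    altloc = c("A", "B", NA), x = c(0, 1, 2), y = 0, z = 0,
    occ = c(0.3, 0.7, 1), b = 10)
  m <- atomic_model(atoms, unit_cell(20, 20, 20))
  picked <- select_atoms(m, "name OG")
  expect_length(picked, 1)
  expect_equal(m$atoms$altloc[picked], "B")
  expect_length(select_atoms(m, "name OG and altloc A"), 1)
})

test_that("torsion matches an independent oracle on random configurations", {
  set.seed(11)
  worst <- 0
  for (rep in 1:100) {
    xyz <- matrix(rnorm(12, sd = 2), 4, 3) + 15
    # reject near-collinear triples to respect the precondition
    bad <- function(a, b, c) {
      v1 <- b - a; v2 <- c - b
      n <- cross_oracle(v1, v2)
      sqrt(sum(n^2)) < 1e-2
    }
    if (bad(xyz[1, ], xyz[2, ], xyz[3, ]) ||
        bad(xyz[2, ], xyz[3, ], xyz[4, ])) next
    m <- point_model(xyz)
    got <- torsion(m, 1, 2, 3, 4)
    want <- oracle_dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-6)
})

test_that("torsion is rigid-motion invariant and order-reversible", {
  set.seed(5)
  for (rep in 1:20) {
    xyz <- matrix(rnorm(12, sd = 3), 4, 3) + 15
    m <- point_model(xyz)
    t0 <- tryCatch(torsion(m, 1, 2, 3, 4), error = function(e) NULL)
    if (is.null(t0)) next
    # random rotation (QR of a random matrix) + translation
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_) * sign(det(qr.Q(qr_)))
    moved <- xyz %*% t(R) + matrix(rnorm(3), 4, 3, byrow = TRUE)
    m2 <- point_model(moved)
    expect_equal(torsion(m2, 1, 2, 3, 4), t0, tolerance = 1e-6)
    expect_equal(torsion(m, 4, 3, 2, 1), t0, tolerance = 1e-6)
  }
})

test_that("torsion handles planarity and rejects collinear atoms", {
  cis <- point_model(rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(torsion(cis, 1, 2, 3, 4), 0, tolerance = 1e-9)
  lin <- point_model(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)))
  expect_error(torsion(lin, 1, 2, 3, 4), "collinear")
  expect_error(torsion(cis, 1, 2, 3, 3), "distinct")
})

test_that("distances, centroid distances and displacements behave", {
  m <- point_model(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(atom_distance(m, 1, 2), 5)
  expect_equal(atom_distance(m, 1, 1), 0)
  # centroid of 6 points symmetric about a known center
  ring <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1)) + 10
  probe <- c(10, 10, 17)
  m2 <- point_model(rbind(probe, ring))
  expect_equal(centroid_distance(m2, 1, 2:7), 7, tolerance = 1e-12)
  # single-atom ring reduces to plain distance
  expect_equal(centroid_distance(m2, 1, 2),
               atom_distance(m2, 1, 2), tolerance = 1e-12)
  expect_error(centroid_distance(m2, 1, "resname NONE"), "empty")
  # two-model displacement in the crystal frame
  toy <- build_toy_system(seed = 2, ion_shift = 1.3)
  expect_equal(atom_distance(toy$dark, "element CL", "element CL",
                             model2 = toy$light), 1.3, tolerance = 1e-9)
})

test_that("rmsd_no_fit matches closed forms and the brute-force oracle", {
  base <- matrix(runif(30, 5, 25), 10, 3)
  mA <- point_model(base)
  expect_equal(rmsd_no_fit(mA, mA, 1:10), 0)
  # one atom displaced by d among n atoms -> d / sqrt(n)
  shifted <- base
  shifted[4, ] <- shifted[4, ] + c(0, 0, 2.5)
  mB <- point_model(shifted)
  expect_equal(rmsd_no_fit(mA, mB, 1:10), 2.5 / sqrt(10), tolerance = 1e-12)
  set.seed(9)
  for (rep in 1:20) {
    a <- matrix(runif(18, 5, 25), 6, 3)
    b <- a + matrix(rnorm(18, sd = 0.7), 6, 3)
    expect_equal(rmsd_no_fit(point_model(a), point_model(b), 1:6),
                 oracle_rmsd(a, b), tolerance = 1e-9)
  }
  # mismatched atom identities are reported
  mC <- point_model(base[1:9, ])
  expect_error(rmsd_no_fit(mA, mC, 1:10), "missing")
})

test_that("plane rotation recovers constructed angles and degenerates", {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- cbind(cos(th), sin(th), 0) * 1.4 + 15
  mA <- point_model(ring)
  expect_equal(plane_rotation(mA, mA, 1:6), 0, tolerance = 1e-9)
  for (ang in c(10, 30, 75)) {
    R <- matrix(c(1, 0, 0,
                  0, cos(ang * pi / 180), -sin(ang * pi / 180),
                  0, sin(ang * pi / 180), cos(ang * pi / 180)), 3, 3,
                byrow = TRUE)
    ctr <- colMeans(ring)
    rotated <- sweep(sweep(ring, 2, ctr) %*% t(R), 2, ctr, `+`)
    expect_equal(plane_rotation(mA, point_model(rotated), 1:6), ang,
                 tolerance = 1e-6)
  }
  line <- cbind(1:5, 1:5, 1:5) + 10
  expect_error(plane_rotation(point_model(line), point_model(line), 1:5),
               "collinear")
})

test_that("helix kink is ~0 for a straight ideal helix, exact for axes", {
  # ideal straight helix of CA atoms; 18 residues per segment is five
  # full turns, so each least-squares axis is the true helix axis
  i <- 1:36
  ca <- cbind(2.3 * cos(i * 100 * pi / 180), 2.3 * sin(i * 100 * pi / 180),
              1.5 * i) + 10
  atoms <- data.frame(chain = "A", resno = i, resname = "ALA", atom = "CA",
                      element = "C", x = ca[, 1], y = ca[, 2], z = ca[, 3],
                      occ = 1, b = 10)
  m <- atomic_model(atoms, unit_cell(80, 80, 80))
  expect_lt(helix_kink(m, "resi 1-18", "resi 19-36"), 1)
  # two straight CA segments at exactly 20 degrees
  u <- c(sin(20 * pi / 180), 0, cos(20 * pi / 180))
  seg1 <- t(sapply(0:5, function(k) c(0, 0, k * 1.5))) + 10
  seg2 <- t(sapply(0:5, function(k) 10 + c(0, 0, 7.5) + k * 1.5 * u))
  atoms2 <- data.frame(chain = "A", resno = 1:12, resname = "ALA",
                       atom = "CA", element = "C",
                       x = c(seg1[, 1], seg2[, 1]),
                       y = c(seg1[, 2], seg2[, 2]),
                       z = c(seg1[, 3], seg2[, 3]), occ = 1, b = 10)
  m2 <- atomic_model(atoms2, unit_cell(50, 50, 50))
  expect_equal(helix_kink(m2, "resi 1-6", "resi 7-12"), 20,
               tolerance = 1e-6)
  expect_error(helix_kink(m2, "resi 1-2", "resi 7-12"), "4 C-alpha")
})

test_that("geometry reports evaluate declared measurements with units", {
  toy <- build_toy_system(seed = 1)
  meas <- list(
    list(name = "chain_torsion", type = "torsion",
         atoms = c("name C12", "name C13", "name C14", "name C15")),
    list(name = "ion_to_nz", type = "distance",
         atoms = c("element CL", "name NZ")),
    list(name = "ion_shift", type = "displacement", a = "element CL"),
    list(name = "tip_rmsd", type = "rmsd", selection = "name C15,NZ"))
  rep <- geometry_report(toy$dark, meas, model2 = toy$light)
  expect_s3_class(rep, "geometry_report")
  expect_equal(rep$value[rep$name == "chain_torsion"], 180,
               tolerance = 1e-6)
  expect_equal(rep$value[rep$name == "ion_shift"], 1.3, tolerance = 1e-9)
  expect_equal(rep$units, c("degrees", "Angstrom", "Angstrom", "Angstrom"))
  expect_true(all(nzchar(rep$atoms)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_geometry_report(rep, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$value, rep$value, tolerance = 1e-9)
})
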