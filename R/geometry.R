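#' Signed dihedral (torsion) angle
#'
#' IUPAC convention: looking from `a2` to `a3`, a clockwise rotation of the
#' far bond relative to the near bond is positive.  Values are reported in
#' (-180, 180]; note that published work sometimes quotes the equivalent
#' angle outside this range (e.g. 187 deg is -173 deg here).
#'
#' @param model An [atomic_model()].
#' @param a1,a2,a3,a4 Atom references (integer ids or single-atom selectors).
#' @return Dihedral angle in degrees, in (-180, 180].
#' @export
torsion <- function(model, a1, a2, a3, a4) {
  ids <- vapply(list(a1, a2, a3, a4), function(r) resolve_atom(model, r),
                integer(1))
  if (anyDuplicated(ids)) stop("torsion needs four distinct atoms")
  p <- atom_xyz(model, ids)
  dihedral_xyz(p[1, ], p[2, ], p[3, ], p[4, ])
}

dihedral_xyz <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("degenerate geometry: three consecutive atoms are collinear")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Interatomic distance
#'
#' Euclidean distance between two atoms in the orthogonal (crystal) frame.
#' With `model2` supplied, `a` is taken from `model` and `b` from `model2`
#' in the shared crystal frame with no superposition, the convention for
#' comparing time-delay structures refined in the same lattice.
#'
#' @param model An [atomic_model()]; `model2` optionally a second model.
#' @param a,b Atom references.
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(model, a, b, model2 = NULL) {
  m2 <- model2 %||% model
  pa <- atom_xyz(model, resolve_atom(model, a))
  pb <- atom_xyz(m2, resolve_atom(m2, b))
  sqrt(sum((pa - pb)^2))
}

#' Distance from an atom to the centroid of a selection
#'
#' The centroid is the unweighted mean position of the selected atoms
#' (e.g. the ionone ring of a retinal chromophore).
#'
#' @param model An [atomic_model()].
#' @param a Atom reference.
#' @param ring Selection (selector string or atom ids); must be non-empty.
#' @return Distance in Angstrom.
#' @export
centroid_distance <- function(model, a, ring) {
  ids <- resolve_selection(model, ring)
  if (length(ids) == 0) stop("empty ring selection")
  ctr <- colMeans(atom_xyz(model, ids))
  pa <- atom_xyz(model, resolve_atom(model, a))
  sqrt(sum((pa - ctr)^2))
}

#' Root-mean-square deviation without superposition
#'
#' Per-atom displacement RMS between two models in the common crystal
#' frame (no fitting), over a selection resolved in both models and
#' matched by (chain, residue, atom name, altloc).
#'
#' @param modelA,modelB [atomic_model()] objects sharing atom identities
#'   over the selection.
#' @param selection Selector string or atom ids (interpreted in `modelA`).
#' @return RMSD in Angstrom.
#' @export
rmsd_no_fit <- function(modelA, modelB, selection) {
  idsA <- resolve_selection(modelA, selection)
  if (length(idsA) == 0) stop("empty selection")
  keyA <- atom_key(modelA, idsA)
  keyB_all <- atom_key(modelB, seq_len(nrow(modelB$atoms)))
  pos <- match(keyA, keyB_all)
  if (anyNA(pos))
    stop("atoms missing from second model: ",
         paste(keyA[is.na(pos)], collapse = ", "))
  d <- atom_xyz(modelA, idsA) - atom_xyz(modelB, pos)
  sqrt(mean(rowSums(d^2)))
}

atom_key <- function(model, ids) {
  a <- model$atoms[ids, ]
  paste(a$chain, a$resno, a$atom, ifelse(is.na(a$altloc), "", a$altloc))
}

#' Rotation angle between best-fit planes of a ring selection
#'
#' Fits a least-squares plane to the ring atoms in each model (smallest
#' principal component of the centered coordinates) and reports the angle
#' between the two plane normals, folded into \[0, 90\] degrees.
#'
#' @param modelA,modelB [atomic_model()] objects.
#' @param ring Selection with at least 3 non-collinear atoms in each model.
#' @return Angle in degrees, in \[0, 90\].
#' @export
plane_rotation <- function(modelA, modelB, ring) {
  n1 <- plane_normal(atom_xyz(modelA, resolve_selection(modelA, ring)))
  n2 <- plane_normal(atom_xyz(modelB, resolve_selection(modelB, ring)))
  ct <- abs(sum(n1 * n2))
  acos(min(1, ct)) * 180 / pi
}

plane_normal <- function(xyz) {
  if (nrow(xyz) < 3) stop("ring needs at least 3 atoms")
  ctr <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(ctr)
  if (sv$d[2] < 1e-6) stop("degenerate geometry: ring atoms are collinear")
  sv$v[, 3]
}

#' Kink angle between two helical segments
#'
#' The axis of each segment is the first principal component of its
#' C-alpha positions (least-squares line), oriented N-to-C; the kink is
#' the angle between the two axes.  Used for transmembrane-helix kink
#' angles such as the bend of TM-G about the retinal-bearing lysine.
#'
#' @param model An [atomic_model()].
#' @param segment1,segment2 Selector strings or atom-id vectors; each must
#'   resolve to >= 4 C-alpha atoms (selectors are automatically restricted
#'   to atoms named CA).
#' @return Kink angle in degrees, in \[0, 180).
#' @export
helix_kink <- function(model, segment1, segment2) {
  ax1 <- segment_axis(model, segment1)
  ax2 <- segment_axis(model, segment2)
  ct <- sum(ax1 * ax2)
  acos(max(-1, min(1, ct))) * 180 / pi
}

segment_axis <- function(model, segment) {
  ids <- resolve_selection(model, segment)
  ids <- ids[model$atoms$atom[ids] == "CA"]
  if (length(ids) < 4) stop("segment needs >= 4 C-alpha atoms")
  ids <- ids[order(model$atoms$chain[ids], model$atoms$resno[ids])]
  xyz <- atom_xyz(model, ids)
  ctr <- sweep(xyz, 2, colMeans(xyz))
  ax <- svd(ctr)$v[, 1]
  if (sum(ax * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) ax <- -ax  # N -> C
  ax
}

#' Evaluate a declared list of geometric measurements
#'
#' Runs named measurements (torsions, distances, centroid distances,
#' no-fit RMSDs, plane rotations, helix kinks, two-model displacements)
#' against one model, or a dark/light model pair for the two-model types.
#' This is the engine behind per-time-delay geometry tables.
#'
#' @param model An [atomic_model()] (the reference, e.g. dark state).
#' @param measurements List of measurement specs; each a list with `name`,
#'   `type` (one of `"torsion"`, `"distance"`, `"centroid_distance"`,
#'   `"rmsd"`, `"plane_rotation"`, `"helix_kink"`, `"displacement"`), and
#'   the arguments that type needs (`atoms` = character vector of atom
#'   references for torsion/distance; `a`/`ring` for centroid_distance;
#'   `selection` for rmsd/plane_rotation/displacement; `segment1`/`segment2`
#'   for helix_kink).  `displacement` is the distance between the same atom
#'   (`a`) in the two models.
#' @param model2 Optional second model for two-model measurement types.
#' @return A `geometry_report` data frame: name, type, value, units, atoms.
#' @export
geometry_report <- function(model, measurements, model2 = NULL) {
  rows <- lapply(measurements, function(m) {
    # configs parsed from YAML/JSON deliver selector lists, not vectors
    for (f in c("atoms", "ring", "selection", "segment1", "segment2"))
      if (!is.null(m[[f]])) m[[f]] <- unlist(m[[f]])
    v <- switch(m$type,
      torsion = torsion(model, m$atoms[1], m$atoms[2], m$atoms[3], m$atoms[4]),
      distance = atom_distance(model, m$atoms[1], m$atoms[2],
                               model2 = if (isTRUE(m$cross)) model2 else NULL),
      centroid_distance = centroid_distance(model, m$a, m$ring),
      rmsd = rmsd_no_fit(model, model2, m$selection),
      plane_rotation = plane_rotation(model, model2, m$selection),
      helix_kink = helix_kink(model, m$segment1, m$segment2),
      displacement = atom_distance(model, m$a, m$a, model2 = model2),
      stop("unknown measurement type: ", m$type))
    units <- if (m$type %in% c("torsion", "plane_rotation", "helix_kink"))
      "degrees" else "Angstrom"
    used <- paste(unlist(m[intersect(names(m),
             c("atoms", "a", "ring", "selection", "segment1", "segment2"))]),
             collapse = " | ")
    data.frame(name = m$name, type = m$type, value = v, units = units,
               atoms = used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("geometry_report", class(out))
  out
}

#' Write a geometry report as TSV or JSON
#'
#' @param report A [geometry_report()] data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_geometry_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
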