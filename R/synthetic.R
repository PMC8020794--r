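#' Build a two-state toy crystal
#'
#' Constructs a pair of P1 atomic models that differ by a localized,
#' exactly known conformational change, emulating the mixed-state regime
#' of a pump-probe crystallography experiment on a retinal protein:
#'
#' * a 10-residue poly-glycine alpha-helix (scaffold scattering matter),
#' * a planar conjugated chain `RLY` of 15 carbons ending in a Schiff-base
#'   nitrogen `NZ` (chromophore mimic),
#' * one chloride ion placed 3.2 A from `NZ`,
#' * about 10 ordered waters at seeded positions.
#'
#' The light state rotates the terminal chain segment (atoms beyond C14)
#' about the C13-C14 bond by `torsion_flip` degrees — flipping the
#' C12-C13-C14-C15 torsion from ~180 deg towards ~(180 + flip) — and
#' displaces the ion by exactly `ion_shift` Angstrom away from `NZ`.
#' All other atoms are identical, and the perturbed atom set is recorded
#' as ground truth.
#'
#' @param seed Integer seed controlling water placement.
#' @param cell_edge P1 cubic cell edge, Angstrom (default 30; must leave
#'   >= 4 A padding around the chain).
#' @param n_waters Number of waters (default 10).
#' @param torsion_flip Signed rotation of the terminal segment in degrees
#'   (default -175: dark torsion 180 deg -> light ~5 deg, mimicking the
#'   all-trans to 13-cis flip).
#' @param ion_shift Ion displacement in Angstrom (default 1.3).
#' @return List with `dark` and `light` [atomic_model()]s and `truth`
#'   (perturbed atom descriptions, the torsion quad, ion shift, flip).
#' @export
build_toy_system <- function(seed = 1, cell_edge = 30, n_waters = 10,
                             torsion_flip = -175, ion_shift = 1.3) {
  n_chain <- 15
  chain_len <- (n_chain + 1) * 1.4 * sin(pi / 3)
  if (cell_edge < chain_len + 8)
    stop("cell_edge too small: chain needs >= 4 A padding on each side")
  ctr <- cell_edge / 2
  # conjugated chain: planar zigzag, bond 1.40 A, 120 deg angles
  i <- seq_len(n_chain + 1)
  cx <- (i - (n_chain + 2) / 2) * 1.4 * sin(pi / 3) + ctr
  cy <- 0.35 * (-1)^i + ctr - 4
  cz <- rep(ctr, n_chain + 1)
  chain <- data.frame(
    chain = "B", resno = 1L, resname = "RLY",
    atom = c(paste0("C", 1:n_chain), "NZ"),
    element = c(rep("C", n_chain), "N"),
    x = cx, y = cy, z = cz, occ = 1, b = 12)
  # chloride 3.2 A from NZ, perpendicular to the chain plane-ish
  nz <- unlist(chain[n_chain + 1, c("x", "y", "z")])
  cl_dir <- c(0.3, 0.6, 0.74); cl_dir <- cl_dir / sqrt(sum(cl_dir^2))
  ion <- data.frame(chain = "C", resno = 1L, resname = "CL", atom = "CL",
                    element = "CL", x = nz[1] + 3.2 * cl_dir[1],
                    y = nz[2] + 3.2 * cl_dir[2], z = nz[3] + 3.2 * cl_dir[3],
                    occ = 1, b = 15)
  helix <- ideal_helix(n_res = 10, origin = c(ctr - 6, ctr + 5, ctr - 2))
  old <- get_seed_state()
  on.exit(restore_seed_state(old))
  set.seed(as.integer(seed))
  waters <- place_waters(n_waters, cell_edge,
                         rbind(as.matrix(chain[, c("x", "y", "z")]),
                               as.matrix(ion[, c("x", "y", "z")]),
                               as.matrix(helix[, c("x", "y", "z")])))
  atoms <- rbind(helix, chain, ion, waters)
  atoms$altloc <- NA_character_
  cell <- unit_cell(cell_edge, cell_edge, cell_edge)
  dark <- atomic_model(atoms, cell, label = "dark")
  # light: rotate atoms beyond C14 about the C13->C14 bond, shift the ion
  light_atoms <- atoms
  quad <- c("C12", "C13", "C14", "C15")
  idx <- function(nm) which(atoms$chain == "B" & atoms$atom == nm)
  p13 <- unlist(atoms[idx("C13"), c("x", "y", "z")])
  p14 <- unlist(atoms[idx("C14"), c("x", "y", "z")])
  moving <- which(atoms$chain == "B" &
                    atoms$atom %in% c("C15", "NZ"))
  rot <- rotate_about_axis(as.matrix(light_atoms[moving, c("x", "y", "z")]),
                           p13, p14, -torsion_flip)
  light_atoms[moving, c("x", "y", "z")] <- rot
  iidx <- which(atoms$chain == "C")
  nz_new <- unlist(light_atoms[which(atoms$chain == "B" & atoms$atom == "NZ"),
                               c("x", "y", "z")])
  ion_pos <- unlist(atoms[iidx, c("x", "y", "z")])
  away <- ion_pos - nz
  away <- away / sqrt(sum(away^2))
  light_atoms[iidx, c("x", "y", "z")] <- ion_pos + ion_shift * away
  light <- atomic_model(light_atoms, cell, label = "light")
  truth <- list(
    torsion_quad = paste("chain B and name", quad),
    moved_atoms = atom_key(dark, c(moving, iidx)),
    ion_selector = "element CL",
    ion_shift = ion_shift, torsion_flip = torsion_flip,
    dark_torsion = torsion(dark, "name C12", "name C13", "name C14",
                           "name C15"),
    light_torsion = torsion(light, "name C12", "name C13", "name C14",
                            "name C15"))
  list(dark = dark, light = light, truth = truth)
}

ideal_helix <- function(n_res, origin, rise = 1.5, twist = 100, r_ca = 2.3) {
  rows <- list()
  for (i in seq_len(n_res)) {
    th <- (i - 1) * twist * pi / 180
    ca <- c(r_ca * cos(th), r_ca * sin(th), (i - 1) * rise)
    # crude backbone placements around CA; scattering matter, not
    # stereochemistry
    nn <- ca + c(-1.0 * sin(th), 1.0 * cos(th), -0.9)
    cc <- ca + c(0.9 * sin(th), -0.9 * cos(th), 1.0)
    oo <- cc + c(0.6 * cos(th), 0.6 * sin(th), 0.9)
    rows[[i]] <- data.frame(
      chain = "A", resno = i, resname = "GLY",
      atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      x = origin[1] + c(nn[1], ca[1], cc[1], oo[1]),
      y = origin[2] + c(nn[2], ca[2], cc[2], oo[2]),
      z = origin[3] + c(nn[3], ca[3], cc[3], oo[3]),
      occ = 1, b = 18)
  }
  do.call(rbind, rows)
}

place_waters <- function(n, cell_edge, occupied, min_dist = 2.4) {
  pos <- matrix(NA_real_, n, 3)
  placed <- 0
  tries <- 0
  while (placed < n && tries < 5000) {
    tries <- tries + 1
    p <- stats::runif(3, 6, cell_edge - 6)
    all_pts <- rbind(occupied, pos[seq_len(placed), , drop = FALSE])
    if (min(sqrt(rowSums(sweep(all_pts, 2, p)^2))) >= min_dist) {
      placed <- placed + 1
      pos[placed, ] <- p
    }
  }
  if (placed < n) stop("could not place waters; cell too crowded")
  data.frame(chain = "W", resno = seq_len(n), resname = "HOH", atom = "O",
             element = "O", x = pos[, 1], y = pos[, 2], z = pos[, 3],
             occ = 1, b = 25)
}

rotate_about_axis <- function(xyz, p_from, p_to, angle_deg) {
  ax <- p_to - p_from
  ax <- ax / sqrt(sum(ax^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(xyz, 2, p_to) %*% t(R), 2, p_to, `+`)
}

get_seed_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_seed_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Define a synthetic two-state experiment
#'
#' Bundles the toy model pair with the mixing fraction, noise level,
#' resolution and seed that [simulate_observed()] uses.
#'
#' @param p_true True excited-state fraction, in (0, 0.5].
#' @param noise_frac Relative amplitude noise, in (0, 0.2) (per
#'   resolution shell; see [simulate_observed()]).
#' @param seed Integer seed (drives both model building and noise).
#' @param d_min Resolution limit, Angstrom.
#' @param ... Passed to [build_toy_system()].
#' @return Object of class `synthetic_experiment`.
#' @export
synthetic_experiment <- function(p_true = 0.05, noise_frac = 0.03, seed = 1,
                                 d_min = 1.8, ...) {
  if (p_true <= 0 || p_true > 0.5) stop("p_true must lie in (0, 0.5]")
  if (noise_frac < 0 || noise_frac >= 0.2)
    stop("noise_frac must lie in [0, 0.2)")
  toy <- build_toy_system(seed = seed, ...)
  structure(list(dark = toy$dark, light = toy$light, truth = toy$truth,
                 p_true = p_true, noise_frac = noise_frac,
                 seed = as.integer(seed), d_min = d_min),
            class = "synthetic_experiment")
}

#' Simulate observed pump and dark amplitude sets
#'
#' The physical model of a partially occupied crystal: the pumped data
#' are the modulus of the complex population-weighted mixture
#' F_mix = (1 - p) F_dark + p F_light, and the dark data the modulus of
#' F_dark, each with independent Gaussian noise whose standard deviation
#' is `noise_frac` times the mean amplitude of the reflection's
#' resolution shell (10 equal-count shells); sigmas are set to the noise
#' level.  Fully deterministic given the experiment seed.
#'
#' @param exp A [synthetic_experiment()].
#' @param method Structure-factor back end (default `"fft"`).
#' @return List with `dark_obs` and `pump_obs` [reflection_set()]s and
#'   the noise-free complex `fc_dark`, `fc_light`.
#' @export
simulate_observed <- function(exp, method = "fft") {
  stopifnot(inherits(exp, "synthetic_experiment"))
  fc_dark <- calc_sf(exp$dark, exp$d_min, method = method)
  fc_light <- calc_sf(exp$light, exp$d_min, method = method)
  fmix <- (1 - exp$p_true) * fc_dark$f + exp$p_true * fc_light$f
  s <- hkl_s(exp$dark$cell, fc_dark$hkl)
  shell <- shell_index(s, 10)
  old <- get_seed_state()
  on.exit(restore_seed_state(old))
  set.seed(exp$seed + 1000003L)
  noisy <- function(amp) {
    sd_shell <- exp$noise_frac * tapply(amp, shell, mean)
    sig <- as.numeric(sd_shell[shell])
    if (exp$noise_frac == 0) sig <- rep(0, length(amp))
    obs <- abs(amp + stats::rnorm(length(amp), 0, ifelse(sig > 0, sig, 0)))
    list(f = obs, sig = ifelse(sig > 0, sig, NA_real_))
  }
  pu <- noisy(Mod(fmix))
  da <- noisy(Mod(fc_dark$f))
  list(
    dark_obs = reflection_set(exp$dark$cell, fc_dark$hkl, da$f, sigf = da$sig,
                              d_min = exp$d_min, label = "dark_obs"),
    pump_obs = reflection_set(exp$dark$cell, fc_dark$hkl, pu$f, sigf = pu$sig,
                              d_min = exp$d_min, label = "pump_obs"),
    fc_dark = fc_dark, fc_light = fc_light)
}

shell_index <- function(s, n_shells) {
  br <- stats::quantile(s, probs = seq(0, 1, length.out = n_shells + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  cut(s, breaks = unique(br), labels = FALSE)
}

#' Write a synthetic experiment to disk
#'
#' Emits `dark.pdb`, `light.pdb` (ground truth), `dark_obs.tsv`,
#' `pump_obs.tsv`, and `manifest.json` recording p_true, noise, seed,
#' resolution and the perturbed atoms.
#'
#' @param exp A [synthetic_experiment()].
#' @param dir Output directory (created if needed).
#' @param method Structure-factor back end for the simulated data.
#' @return Invisibly, the manifest as a list (with file paths).
#' @export
write_experiment <- function(exp, dir, method = "fft") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obs <- simulate_observed(exp, method = method)
  paths <- list(dark_model = file.path(dir, "dark.pdb"),
                light_model = file.path(dir, "light.pdb"),
                dark_obs = file.path(dir, "dark_obs.tsv"),
                pump_obs = file.path(dir, "pump_obs.tsv"),
                manifest = file.path(dir, "manifest.json"))
  write_model(exp$dark, paths$dark_model)
  write_model(exp$light, paths$light_model)
  write_reflections(obs$dark_obs, paths$dark_obs)
  write_reflections(obs$pump_obs, paths$pump_obs)
  manifest <- list(p_true = exp$p_true, noise_frac = exp$noise_frac,
                   seed = exp$seed, d_min = exp$d_min,
                   truth = exp$truth[c("ion_shift", "torsion_flip",
                                       "dark_torsion", "light_torsion",
                                       "moved_atoms", "ion_selector",
                                       "torsion_quad")],
                   files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(manifest, list(paths = paths)))
}

#' End-to-end population recovery on a synthetic experiment
#'
#' Runs the full analysis chain on one simulated experiment — simulate
#' observed data, scale pump onto dark, difference, weight, scan the
#' extrapolation factor against the ground-truth mask atoms — and
#' reports the recovered population transfer next to the simulated one.
#'
#' @param exp A [synthetic_experiment()].
#' @param mask_atoms Mask selection for [next_scan()]; default the
#'   experiment's displaced atoms (ion + flipped chain tip).
#' @param n_grid Candidate factors (default 2:200).
#' @param ... Passed to [next_scan()].
#' @return List: `scan`, `pt` (percent), `p_recovered` (fraction),
#'   `p_true`, `rel_err`, `scale`, and the weighted difference set.
#' @export
recover_population <- function(exp, mask_atoms = c("element CL",
                                                   "chain B and name C15,NZ"),
                               n_grid = 2:200, ...) {
  stopifnot(inherits(exp, "synthetic_experiment"))
  obs <- simulate_observed(exp)
  sc <- scale_datasets(obs$dark_obs, obs$pump_obs)
  ds <- difference_amplitudes(sc$scaled, obs$dark_obs)
  ds <- weight_differences(ds)
  scan <- next_scan(obs$fc_dark, ds, exp$dark, mask_atoms,
                    n_grid = n_grid, ...)
  pt <- population_transfer(scan$n_ext)
  list(scan = scan, pt = pt$pt, p_recovered = pt$pt / 100,
       p_true = exp$p_true, rel_err = (pt$pt / 100 - exp$p_true) / exp$p_true,
       scale = sc, ds = ds, obs = obs)
}
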