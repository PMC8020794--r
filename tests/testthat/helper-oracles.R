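# Independent brute-force oracles and small fixtures shared across tests.
# Oracles deliberately use different formulations than the package code.

# dihedral via the Gram-Schmidt / projection construction (not atan2 of
# the cross-product pair used in the package)
oracle_dihedral <- function(p1, p2, p3, p4) {
  # geometric definition: look along the central bond (p2 -> p3),
  # project the outer bonds onto the perpendicular plane, and measure
  # the clockwise angle from the p1 side to the p4 side
  b2u <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  perp <- function(u) u - sum(u * b2u) * b2u
  v <- perp(p1 - p2)
  w <- perp(p4 - p3)
  ang <- -atan2(sum(cross_oracle(v, w) * b2u), sum(v * w)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

cross_oracle <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

oracle_rmsd <- function(xyzA, xyzB) {
  stopifnot(nrow(xyzA) == nrow(xyzB))
  total <- 0
  for (i in seq_len(nrow(xyzA)))
    total <- total + sum((xyzA[i, ] - xyzB[i, ])^2)
  sqrt(total / nrow(xyzA))
}

# structure factor by naive per-atom loop (scalar accumulation; the
# package uses vectorized matrix products)
oracle_sf <- function(cell, atoms_frac, hkl_row) {
  s <- trxmap:::hkl_s(cell, matrix(hkl_row, 1))
  q2 <- (s / 2)^2
  acc <- 0 + 0i
  for (j in seq_len(nrow(atoms_frac))) {
    f <- trxmap::form_factor(atoms_frac$element[j], s)
    ph <- 2 * pi * sum(hkl_row * c(atoms_frac$fx[j], atoms_frac$fy[j],
                                   atoms_frac$fz[j]))
    acc <- acc + atoms_frac$occ[j] * f * exp(-atoms_frac$b[j] * q2) *
      complex(modulus = 1, argument = ph)
  }
  acc
}

# a tiny deterministic model: n random atoms in a P1 box, kept at least
# min_sep apart so density peaks stay resolvable
random_model <- function(n = 8, seed = 42, edge = 12, label = "rand",
                         min_sep = 2.2) {
  set.seed(seed)
  pos <- matrix(NA_real_, n, 3)
  placed <- 0
  while (placed < n) {
    p <- runif(3, 2, edge - 2)
    if (placed == 0 ||
        min(sqrt(rowSums(sweep(pos[seq_len(placed), , drop = FALSE],
                               2, p)^2))) >= min_sep) {
      placed <- placed + 1
      pos[placed, ] <- p
    }
  }
  atoms <- data.frame(
    chain = "A", resno = seq_len(n), resname = "UNK",
    atom = paste0("X", seq_len(n)),
    element = sample(c("C", "N", "O", "S"), n, replace = TRUE),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    occ = 1, b = runif(n, 5, 25))
  atomic_model(atoms, unit_cell(edge, edge, edge), label = label)
}

# place named atoms at given coordinates in a generous P1 cell
point_model <- function(xyz, elements = NULL, names = NULL, edge = 40,
                        b = 10) {
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  atoms <- data.frame(
    chain = "A", resno = seq_len(n), resname = "UNK",
    atom = names %||% paste0("X", seq_len(n)),
    element = elements %||% rep("C", n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = b)
  atomic_model(atoms, unit_cell(edge, edge, edge), label = "points")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cached default synthetic experiment for reuse across test files
toy_cache <- new.env()
cached_experiment <- function(p = 0.05, noise = 0.03, seed = 7) {
  key <- paste(p, noise, seed)
  if (is.null(toy_cache[[key]]))
    toy_cache[[key]] <- synthetic_experiment(p_true = p, noise_frac = noise,
                                             seed = seed)
  toy_cache[[key]]
}
obs_cache <- new.env()
cached_observed <- function(p = 0.05, noise = 0.03, seed = 7) {
  key <- paste(p, noise, seed)
  if (is.null(obs_cache[[key]]))
    obs_cache[[key]] <- simulate_observed(cached_experiment(p, noise, seed))
  obs_cache[[key]]
}
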