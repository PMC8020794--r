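#' Triclinic unit cell
#'
#' Constructs a unit-cell object holding the six cell parameters and the
#' derived orthogonalization machinery used by all reciprocal-space and
#' map operations.
#'
#' @param a,b,c Cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` with elements `a,b,c,alpha,beta,
#'   gamma`, the orthogonalization matrix `orth` (fractional -> Cartesian,
#'   PDB convention: a along x, b in the xy plane), its inverse `frac`,
#'   and the cell volume `volume` in cubic Angstrom.
#' @examples
#' uc <- unit_cell(30, 30, 30)
#' uc$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  # PDB/CCP4 orthogonalization: a along x, b in xy plane
  v <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v <= 0) stop("cell angles give a non-positive metric (not a valid cell)")
  vol <- a * b * c * sqrt(v)
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0, vol / (a * b * sg)
  ), nrow = 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 orth = orth, frac = solve(orth), volume = vol),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

is_unit_cell <- function(x) inherits(x, "unit_cell")

same_cell <- function(c1, c2, tol = 1e-3) {
  all(abs(unlist(c1[c("a", "b", "c", "alpha", "beta", "gamma")]) -
          unlist(c2[c("a", "b", "c", "alpha", "beta", "gamma")])) < tol)
}

#' Fractional/orthogonal coordinate conversion
#'
#' @param cell A [unit_cell()].
#' @param xyz Matrix (n x 3) of coordinates (rows are points).
#' @return Matrix (n x 3) of converted coordinates.
#' @export
frac2orth <- function(cell, xyz) {
  xyz <- rbind(xyz)
  t(cell$orth %*% t(xyz))
}

#' @rdname frac2orth
#' @export
orth2frac <- function(cell, xyz) {
  xyz <- rbind(xyz)
  t(cell$frac %*% t(xyz))
}

# |s*| = 1/d for rows of an hkl matrix
hkl_s <- function(cell, hkl) {
  hkl <- rbind(hkl)
  recip <- t(cell$frac)            # rows of frac are a*, b*, c* components
  sv <- hkl %*% recip              # reciprocal-lattice vectors, 1/Angstrom
  sqrt(rowSums(sv * sv))
}

# d-spacing in Angstrom
hkl_d <- function(cell, hkl) 1 / hkl_s(cell, hkl)

# Enumerate the Friedel hemisphere of Miller indices with d >= d_min
# (excluding 000).  Hemisphere convention: h>0, or h=0 & k>0, or h=k=0 & l>0.
miller_hemisphere <- function(cell, d_min) {
  stopifnot(d_min > 0)
  lim <- function(len) as.integer(ceiling(len / d_min)) + 1L
  hm <- lim(cell$a); km <- lim(cell$b); lm <- lim(cell$c)
  g <- expand.grid(h = -hm:hm, k = -km:km, l = -lm:lm)
  g <- as.matrix(g)
  keep <- (g[, 1] > 0) | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  g <- g[keep, , drop = FALSE]
  s <- hkl_s(cell, g)
  g <- g[s <= 1 / d_min + 1e-12, , drop = FALSE]
  g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
}

# FFT-friendly grid size >= n (factors 2,3,5 only, even)
nice_grid_size <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  if (n %% 2L == 1L) n <- n + 1L
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 2L
  }
}

# Grid dimensions for a cell at given max spacing (Angstrom)
map_grid_dim <- function(cell, spacing) {
  vapply(c(cell$a, cell$b, cell$c),
         function(len) nice_grid_size(len / spacing), integer(1))
}
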