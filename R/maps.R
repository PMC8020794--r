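#' Real-space density map
#'
#' A density grid over the unit cell.  `values` is a 3D array whose index
#' `(i, j, k)` corresponds to fractional position `((i-1)/nx, ...)`; maps
#' are either in electrons/A^3 or sigma-scaled (mean 0, sd 1).
#'
#' @param values 3D numeric array.
#' @param cell A [unit_cell()].
#' @param sigma_scaled Logical: are values in sigma units?
#' @param mean_raw,sigma_raw Mean and sd of the raw (unscaled) map.
#' @param label Provenance label.
#' @return Object of class `density_map`.
#' @export
density_map <- function(values, cell, sigma_scaled = FALSE,
                        mean_raw = mean(values), sigma_raw = stats::sd(values),
                        label = "map") {
  stopifnot(is.array(values), length(dim(values)) == 3, is_unit_cell(cell))
  structure(list(values = values, cell = cell, dims = dim(values),
                 sigma_scaled = sigma_scaled, mean_raw = mean_raw,
                 sigma_raw = sigma_raw, label = label),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map '%s': %d x %d x %d grid, %s (raw mean %.4g, sd %.4g)\n",
              x$label, x$dims[1], x$dims[2], x$dims[3],
              if (x$sigma_scaled) "sigma-scaled" else "e-/A^3",
              x$mean_raw, x$sigma_raw))
  invisible(x)
}

# place hemisphere F(h) plus Friedel mates into the FFT array and invert:
# rho(x) = (1/V) sum_h F(h) exp(-2 pi i h.x)
synthesize_grid <- function(cell, hkl, f, dims) {
  both_hkl <- rbind(hkl, -hkl)
  both_f <- c(f, Conj(f))
  arr <- array(0 + 0i, dims)
  idx <- both_hkl %% matrix(dims, nrow(both_hkl), 3, byrow = TRUE)
  lin <- idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3]) + 1
  if (anyDuplicated(lin))
    stop("grid too coarse: distinct reflections alias to one grid point")
  arr[lin] <- both_f
  Re(stats::fft(arr)) / cell$volume
}

#' Fourier synthesis of a density map
#'
#' Synthesizes rho(x) = (1/V) sum_h F(h) e^{-2 pi i h.x} from amplitudes
#' and phases over the Friedel hemisphere (mates added internally;
#' F(000) is omitted, so raw maps have near-zero mean).
#'
#' @param source A [reflection_set()] with phases, or a [complex_sf()].
#' @param grid Grid dimensions (length-3 integer) or `NULL` to choose
#'   from `spacing`.
#' @param spacing Target grid spacing in Angstrom (default `d_min`/3).
#' @param sigma_scale If `TRUE` (default), subtract the mean and divide
#'   by the standard deviation over all grid points.
#' @return A [density_map()].
#' @export
fourier_map <- function(source, grid = NULL, spacing = NULL,
                        sigma_scale = TRUE) {
  if (inherits(source, "complex_sf")) {
    hkl <- source$hkl; f <- source$f
    cell <- source$cell; d_min <- source$d_min; label <- source$label
  } else if (inherits(source, "reflection_set")) {
    miss <- sum(is.na(source$data$phi))
    if (miss > 0) stop(miss, " reflection(s) lack phases")
    hkl <- hkl_matrix(source)
    f <- source$data$f * exp(1i * source$data$phi * pi / 180)
    cell <- source$cell; d_min <- source$d_min; label <- source$label
  } else stop("source must be a reflection_set (with phases) or complex_sf")
  dims <- grid %||% map_grid_dim(cell, (spacing %||% (d_min / 3)))
  vals <- synthesize_grid(cell, hkl, f, dims)
  m <- density_map(vals, cell, label = label)
  if (sigma_scale) m <- sigma_scale_map(m)
  m
}

#' Sigma-scale a map (mean 0, sd 1)
#'
#' @param map A [density_map()].
#' @return The sigma-scaled map; raw mean/sd are retained as metadata.
#' @export
sigma_scale_map <- function(map) {
  if (map$sigma_scaled) return(map)
  s <- stats::sd(map$values)
  if (s == 0) s <- 1                      # constant map stays constant
  map$values <- (map$values - mean(map$values)) / s
  map$sigma_scaled <- TRUE
  map
}

#' Weighted Fourier difference map
#'
#' Synthesizes the sigma-scaled difference map from weighted amplitude
#' differences and dark-model phases: coefficients w * delta_f with phase
#' Phi_dark.
#'
#' @param ds A [difference_set()], normally after [weight_differences()]
#'   (a message notes when it is unweighted).
#' @param dark_phases A [reflection_set()] with phases, or a
#'   [complex_sf()] of the dark model, covering the difference set.
#' @param grid,spacing Grid control as in [fourier_map()].
#' @param sigma_scale Sigma-scale the result (default `TRUE`).
#' @return A [density_map()] with weighting metadata in its label.
#' @export
difference_map <- function(ds, dark_phases, grid = NULL, spacing = NULL,
                           sigma_scale = TRUE) {
  stopifnot(inherits(ds, "difference_set"))
  if (!ds$weighted)
    message("note: difference set is unweighted")
  ph <- phases_for(dark_phases, ds$data)
  f <- ds$data$weight * ds$data$delta_f * exp(1i * ph)
  dims <- grid %||% map_grid_dim(ds$cell, (spacing %||% (ds$d_min / 3)))
  vals <- synthesize_grid(ds$cell, hkl_matrix(ds), f, dims)
  m <- density_map(vals, ds$cell,
                   label = sprintf("DMAP[%s - %s]%s", ds$labels["pump"],
                                   ds$labels["dark"],
                                   if (ds$weighted)
                                     sprintf(" alpha=%.2f", ds$alpha) else ""))
  if (sigma_scale) m <- sigma_scale_map(m)
  m
}

# phases (radians) aligned to the rows of a data frame with h,k,l
phases_for <- function(phase_source, d) {
  if (inherits(phase_source, "complex_sf")) {
    key <- paste(phase_source$hkl[, 1], phase_source$hkl[, 2],
                 phase_source$hkl[, 3])
    pos <- match(hkl_key(d), key)
    if (anyNA(pos))
      stop(sum(is.na(pos)), " reflection(s) lack phases in the phase source")
    Arg(phase_source$f)[pos]
  } else if (inherits(phase_source, "reflection_set")) {
    pos <- match(hkl_key(d), hkl_key(phase_source$data))
    phi <- phase_source$data$phi[pos]
    if (anyNA(phi))
      stop(sum(is.na(phi)), " reflection(s) lack phases in the phase source")
    phi * pi / 180
  } else stop("phase source must be a reflection_set or complex_sf")
}

#' Write / read a CCP4/MRC format map
#'
#' Minimal mode-2 (32-bit float) CCP4 map I/O covering the whole unit
#' cell, little-endian, no symmetry block.
#'
#' @param map A [density_map()].
#' @param path File path.
#' @return `write_ccp4_map`: invisibly, `path`; `read_ccp4_map`: a
#'   [density_map()].
#' @export
write_ccp4_map <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- map$dims
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2); wi(c(0, 0, 0)); wi(d)
  cl <- map$cell
  wf(c(cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma))
  wi(c(1, 2, 3))
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(1); wi(0); wi(rep(0, 2))             # ISPG, NSYMBT, extra
  writeChar("MAP ", con, 4, eos = NULL)
  wi(16708)                                # little-endian machine stamp
  wf(stats::sd(map$values))
  wi(0)                                    # NLABL
  writeBin(raw(800), con)                  # label block
  wf(as.vector(map$values))
  invisible(path)
}

#' @rdname write_ccp4_map
#' @export
read_ccp4_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported CCP4 map mode: ", mode)
  ri(3); mxyz <- ri(3)
  cp <- rf(6)
  ri(3); rf(3); ri(1)
  nsym <- ri(1)
  ri(2); readChar(con, 4); ri(1); rf(1); ri(1)
  readBin(con, "raw", 800)
  if (nsym > 0) readBin(con, "raw", nsym)
  vals <- array(rf(prod(d)), d)
  density_map(vals, unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6]),
              label = basename(path))
}
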