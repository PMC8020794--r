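#' Form amplitude differences between pump and dark data
#'
#' Per common reflection, delta_f = |F_pump| - |F_dark| and
#' sigma_delta = sqrt(sigma_pump^2 + sigma_dark^2).  Reflections present
#' in only one set are dropped and counted in the completeness report
#' (zero-filling would bias difference maps).  Weights start at 1; apply
#' [weight_differences()] before map synthesis or extrapolation.
#'
#' @param pump A [reflection_set()] of pumped amplitudes, already scaled
#'   onto `dark` (see [scale_datasets()]); a message is emitted if no
#'   scaling provenance is attached.
#' @param dark A [reflection_set()] of dark amplitudes.
#' @param min_common Minimum number of common reflections (default 50).
#' @return Object of class `difference_set`: data frame `data` with
#'   h, k, l, delta_f, sig_delta, weight, plus `cell`, `d_min`, parent
#'   `labels`, and a `report` listing dropped-reflection counts.
#' @export
difference_amplitudes <- function(pump, dark, min_common = 50) {
  stopifnot(inherits(pump, "reflection_set"),
            inherits(dark, "reflection_set"))
  if (is.null(attr(pump, "scaled_to")))
    message("note: pump set carries no scaling provenance; ",
            "scale_datasets() is recommended before differencing")
  kp <- hkl_key(pump$data); kd <- hkl_key(dark$data)
  common <- intersect(kp, kd)
  if (length(common) < min_common)
    stop("only ", length(common), " common reflections")
  ip <- match(common, kp); id <- match(common, kd)
  sig <- sqrt(ifelse(is.na(pump$data$sigf[ip]), 0, pump$data$sigf[ip])^2 +
              ifelse(is.na(dark$data$sigf[id]), 0, dark$data$sigf[id])^2)
  if (all(is.na(pump$data$sigf)) && all(is.na(dark$data$sigf)))
    sig <- rep(NA_real_, length(common))
  d <- data.frame(h = pump$data$h[ip], k = pump$data$k[ip],
                  l = pump$data$l[ip],
                  delta_f = pump$data$f[ip] - dark$data$f[id],
                  sig_delta = sig, weight = 1)
  d <- d[order(d$h, d$k, d$l), ]
  rownames(d) <- NULL
  structure(list(cell = dark$cell, data = d,
                 d_min = max(pump$d_min, dark$d_min),
                 labels = c(pump = pump$label, dark = dark$label),
                 report = list(n_common = length(common),
                               dropped_from_pump = length(kp) - length(common),
                               dropped_from_dark = length(kd) - length(common)),
                 weighted = FALSE, alpha = NA_real_),
            class = "difference_set")
}

#' @export
print.difference_set <- function(x, ...) {
  cat(sprintf("difference_set [%s - %s]: %d reflections to %.2f A (%s)\n",
              x$labels["pump"], x$labels["dark"], nrow(x$data), x$d_min,
              if (x$weighted) sprintf("q-weighted, alpha=%.2f", x$alpha)
              else "unweighted"))
  r <- x$report
  cat(sprintf("  dropped: %d pump-only, %d dark-only\n",
              r$dropped_from_pump, r$dropped_from_dark))
  invisible(x)
}

#' Weight amplitude differences to suppress outliers
#'
#' The q-weighting scheme of the difference-Fourier lineage:
#' w_h = 1 / (1 + sigma_h^2/<sigma^2> + alpha * delta_h^2/<delta^2>),
#' with means taken over the set.  Weighted delta_f (w * delta_f) feeds
#' all downstream map synthesis; extrapolation uses mean-normalized
#' weights so the overall amplitude scale — and with it the physical
#' meaning of the extrapolation factor — is preserved.
#'
#' @param ds A [difference_set()].
#' @param alpha Strength of the outlier term (dimensionless, default 1);
#'   `alpha = 0` weights on sigma alone.
#' @return The difference set with `weight` filled in and weighting
#'   metadata recorded.
#' @export
weight_differences <- function(ds, alpha = 1) {
  stopifnot(inherits(ds, "difference_set"))
  d <- ds$data
  if (all(d$delta_f == 0)) stop("all differences are zero; weights undefined")
  sig2 <- d$sig_delta^2
  term_sig <- if (all(is.na(sig2))) {
    message("note: no sigmas present; weighting on delta_f magnitude only")
    0
  } else sig2 / mean(sig2)
  term_out <- alpha * d$delta_f^2 / mean(d$delta_f^2)
  ds$data$weight <- 1 / (1 + term_sig + term_out)
  ds$weighted <- TRUE
  ds$alpha <- alpha
  ds
}
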