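# Cromer-Mann atomic scattering factors, 4-Gaussian + constant:
#   f(q) = sum_i a_i exp(-b_i q^2) + c,  q = sin(theta)/lambda = s/2, s = 1/d.
# Coefficients from International Tables Vol. C.  Chloride uses the Cl1-
# ionic species: the chromophore counter-ion is an anion and its low-angle
# scattering (18 e) differs measurably from neutral Cl.
.cromer_mann <- list(
  H  = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
            b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P  = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
            b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S  = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
            b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  CL = list(a = c(18.2915, 7.20840, 6.53370, 2.33860),   # Cl1- (anion)
            b = c(0.006600, 1.17170, 19.5424, 60.4486), c = -16.378)
)

ff_coefficients <- function(element) {
  el <- toupper(trimws(element))
  bad <- setdiff(unique(el), names(.cromer_mann))
  if (length(bad) > 0)
    stop("no scattering coefficients for element(s): ", paste(bad, collapse = ", "))
  .cromer_mann[el]
}

#' Atomic form factor
#'
#' Evaluates the Cromer-Mann scattering factor of an element at reciprocal
#' resolution `s = 1/d` (per Angstrom).  Chloride (`"CL"`) is modeled as the
#' Cl- anion.
#'
#' @param element Element symbol; one of H, C, N, O, P, S, CL.
#' @param s Numeric vector of 1/d values (1/Angstrom).
#' @return Numeric vector of scattering factors in electrons.
#' @examples
#' form_factor("C", 0)     # ~6 electrons
#' form_factor("CL", 0)    # ~18 electrons (anion)
#' @export
form_factor <- function(element, s) {
  cf <- ff_coefficients(element)[[1]]
  q2 <- (s / 2)^2
  out <- rep(cf$c, length(s))
  for (i in 1:4) out <- out + cf$a[i] * exp(-cf$b[i] * q2)
  out
}
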