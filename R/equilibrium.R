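#' Equilibrium classical/hybrid occupancy under an E-site inhibitor
#'
#' The four-state binding model has states Classical, Hybrid, Classical-drug
#' and Hybrid-drug with Boltzmann weights `1`, `K0`, `x` and `x / K2`, where
#' `x = [I] / KI`.  The fraction of ribosomes in a classical state is then
#'
#' \deqn{f_c = \frac{1 + x}{1 + K_0 + x (1 + 1/K_2)}}
#'
#' which interpolates between the drug-free limit `1 / (1 + K0)` and the
#' saturating limit `1 / (1 + 1/K2)`.
#'
#' @param thermo A [thermo_params()] object.
#' @param concentration Drug concentration(s), uM; non-negative (`Inf`
#'   allowed for the saturation limit).
#'
#' @return A tibble with columns `concentration`, `f_classical`, `f_hybrid`.
#' @examples
#' th <- thermo_params(K0 = 4, K2 = 10, KI = 10)
#' equilibrium_occupancy(th, c(0, 10, Inf))
#' @export
equilibrium_occupancy <- function(thermo, concentration) {
  stopifnot(inherits(thermo, "thermo_params"))
  if (any(is.na(concentration)) || any(concentration < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  fc <- predict_fraction_classical(thermo, concentration)
  tibble::tibble(
    concentration = concentration,
    f_classical = fc,
    f_hybrid = 1 - fc
  )
}

#' Predicted fraction of classical-state ribosomes
#'
#' The classical-state component of [equilibrium_occupancy()]; this is the
#' isotherm fitted to fraction-classical titration data by
#' [fit_titration()].
#'
#' @inheritParams equilibrium_occupancy
#' @return Numeric vector of classical-state fractions, same length as
#'   `concentration`.
#' @examples
#' predict_fraction_classical(thermo_params(4, 10, 10), 0)  # 1 / (1 + K0)
#' @export
predict_fraction_classical <- function(thermo, concentration) {
  stopifnot(inherits(thermo, "thermo_params"))
  if (any(is.na(concentration)) || any(concentration < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  x <- concentration / thermo$KI
  ifelse(is.infinite(x),
         1 / (1 + 1 / thermo$K2),
         (1 + x) / (1 + thermo$K0 + x * (1 + 1 / thermo$K2)))
}
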