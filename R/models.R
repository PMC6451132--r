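#' Three-state tRNA conformational model for a pre-translocation ribosome
#'
#' Defines the FRET states of a pre-translocation 80S ribosome carrying
#' donor-labelled P-site tRNA and acceptor-labelled A-site tRNA.  Both
#' species presets use the published three-state description: a high-FRET
#' Classical (A/A, P/P) state and two hybrid states, Hybrid1 (A/P, P/E) and
#' Hybrid2 (A/A, P/E), with Gaussian emission widths.
#'
#' Defaults are the per-species state means and SDs determined for yeast
#' (0.65 +/- 0.04, 0.40 +/- 0.06, 0.22 +/- 0.05) and human
#' (0.71 +/- 0.05, 0.44 +/- 0.06, 0.26 +/- 0.07) pre-translocation
#' complexes.
#'
#' @param species `"yeast"` or `"human"`; selects the preset state means/SDs.
#' @param states Optional tibble with columns `state`, `fret_mean`,
#'   `fret_sd` overriding the preset.  Must contain exactly the three states
#'   `Classical`, `Hybrid1`, `Hybrid2` with strictly decreasing means.
#' @param hybrid_split Fraction of total hybrid occupancy assigned to the
#'   Hybrid2 state, in `[0, 1]`.  Defaults to 0.6 for yeast (which favours
#'   Hybrid2) and 0.4 for human (which favours Hybrid1).
#'
#' @return A tibble of class `fret_model` with columns `state`, `fret_mean`,
#'   `fret_sd` and attributes `species` and `hybrid_split`.
#' @examples
#' fret_model("yeast")
#' fret_model("human", hybrid_split = 0.5)
#' @export
fret_model <- function(species = c("yeast", "human"), states = NULL,
                       hybrid_split = NULL) {
  species <- match.arg(species)
  if (is.null(states)) {
    states <- switch(species,
      yeast = tibble::tibble(
        state = c("Classical", "Hybrid1", "Hybrid2"),
        fret_mean = c(0.65, 0.40, 0.22),
        fret_sd = c(0.04, 0.06, 0.05)
      ),
      human = tibble::tibble(
        state = c("Classical", "Hybrid1", "Hybrid2"),
        fret_mean = c(0.71, 0.44, 0.26),
        fret_sd = c(0.05, 0.06, 0.07)
      )
    )
  }
  if (is.null(hybrid_split)) {
    hybrid_split <- switch(species, yeast = 0.6, human = 0.4)
  }
  out <- tibble::as_tibble(states)
  attr(out, "species") <- species
  attr(out, "hybrid_split") <- hybrid_split
  class(out) <- c("fret_model", class(out))
  validate_fret_model(out)
}

validate_fret_model <- function(model) {
  stopifnot(is.data.frame(model))
  if (!all(c("state", "fret_mean", "fret_sd") %in% names(model))) {
    stop("a fret_model needs columns state, fret_mean, fret_sd", call. = FALSE)
  }
  if (nrow(model) != 3L ||
      !identical(model$state, c("Classical", "Hybrid1", "Hybrid2"))) {
    stop("a fret_model has exactly the states Classical, Hybrid1, Hybrid2, in that order",
         call. = FALSE)
  }
  if (any(diff(model$fret_mean) >= 0)) {
    stop("FRET means must decrease strictly from Classical to Hybrid2", call. = FALSE)
  }
  if (any(model$fret_sd <= 0)) stop("FRET state widths must be positive", call. = FALSE)
  lo <- model$fret_mean - 2 * model$fret_sd
  hi <- model$fret_mean + 2 * model$fret_sd
  if (any(lo < -0.2) || any(hi > 1.2)) {
    stop("state means +/- 2 SD must stay within [-0.2, 1.2]", call. = FALSE)
  }
  hs <- attr(model, "hybrid_split")
  if (!is.numeric(hs) || hs < 0 || hs > 1) {
    stop("hybrid_split must lie in [0, 1]", call. = FALSE)
  }
  model
}

#' Thermodynamic parameters of the drug-binding model
#'
#' Parameters of the four-state equilibrium binding model relating the
#' classical/hybrid tRNA equilibrium to E-site inhibitor concentration:
#' `K0` and `K2` are the dimensionless classical-to-hybrid equilibrium
#' constants on the drug-free and drug-bound ribosome, and `KI` is the drug
#' dissociation constant in the same concentration units as the titration
#' (conventionally uM).
#'
#' @param K0 Classical-to-hybrid equilibrium constant, drug-free ribosome.
#' @param K2 Classical-to-hybrid equilibrium constant, drug-bound ribosome.
#' @param KI Drug dissociation constant (uM).
#'
#' @return A list of class `thermo_params`.
#' @examples
#' thermo_params(K0 = 4, K2 = 10, KI = 10)
#' @export
thermo_params <- function(K0, K2, KI) {
  if (!all(is.finite(c(K0, K2, KI))) || any(c(K0, K2, KI) <= 0)) {
    stop("K0, K2 and KI must all be strictly positive and finite", call. = FALSE)
  }
  structure(list(K0 = K0, K2 = K2, KI = KI), class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("<thermo_params> K0 = %g, K2 = %g, KI = %g uM\n", x$K0, x$K2, x$KI))
  invisible(x)
}

#' Photophysical and acquisition parameters for trace simulation
#'
#' Camera/fluorophore parameters used when rendering donor and acceptor
#' intensity traces.  The 40 ms frame duration matches typical smFRET
#' acquisition of tRNA dynamics; intensities are in arbitrary camera units.
#'
#' @param total_intensity_mean Mean total (donor + acceptor) intensity per
#'   frame before photobleaching.
#' @param shot_noise_sd Per-channel additive noise SD while the fluorophores
#'   are emitting.
#' @param background_sd Per-channel noise SD after photobleaching (and
#'   during donor blinks).
#' @param bleach_mean_lifetime Mean photobleaching lifetime, seconds
#'   (exponential).
#' @param blink_rate Donor blinking rate, events per second.
#' @param blink_mean_duration Mean blink duration, seconds (exponential).
#' @param frame_dt Frame duration, seconds.
#' @param n_frames Number of recorded frames per trace.
#'
#' @return A list of class `photophysics`.
#' @examples
#' photophysics()
#' @export
photophysics <- function(total_intensity_mean = 1000, shot_noise_sd = 40,
                         background_sd = 30, bleach_mean_lifetime = 8,
                         blink_rate = 0.02, blink_mean_duration = 0.12,
                         frame_dt = 0.040, n_frames = 600) {
  pos <- c(total_intensity_mean, background_sd, bleach_mean_lifetime,
           blink_mean_duration, frame_dt, n_frames)
  nonneg <- c(shot_noise_sd, blink_rate)
  if (!all(is.finite(c(pos, nonneg))) || any(pos <= 0) || any(nonneg < 0)) {
    stop("photophysics parameters must be positive (shot_noise_sd and blink_rate may be zero)",
         call. = FALSE)
  }
  structure(list(
    total_intensity_mean = total_intensity_mean,
    shot_noise_sd = shot_noise_sd,
    background_sd = background_sd,
    bleach_mean_lifetime = bleach_mean_lifetime,
    blink_rate = blink_rate,
    blink_mean_duration = blink_mean_duration,
    frame_dt = frame_dt,
    n_frames = as.integer(n_frames)
  ), class = "photophysics")
}
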