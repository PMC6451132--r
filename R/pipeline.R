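#' Full smFRET titration analysis on one simulated dataset
#'
#' Runs the complete analysis chain -- trace QC, FRET computation,
#' per-concentration HMM fitting (emission parameters fixed at the species'
#' state values by default), Viterbi idealization, pooled
#' fraction-classical points with bootstrap SEMs, and the weighted
#' isotherm fit -- on a titration simulated under known thermodynamics.
#'
#' @param model A [fret_model()].
#' @param thermo Generating [thermo_params()].
#' @param concentrations Titration concentrations, uM (must include 0).
#' @param n_traces Traces simulated per concentration.
#' @param seed Master seed for the whole replicate.
#' @param photo A [photophysics()] object.
#' @param criteria A [qc_criteria()] object.
#' @param spec Optional [hmm_spec()]; defaults to fixed emissions at the
#'   model's state values.
#' @param n_boot Bootstrap resamples for the per-point SEM.
#' @param dwell_mean Simulated mean state dwell time, seconds.
#'
#' @return A list of class `titration_pipeline` with elements `fit`
#'   (a [fit_titration()] result), `points`, `qc_pass_rate` and
#'   `n_traces_kept`.
#' @examples
#' \donttest{
#' pl <- titration_pipeline(fret_model("yeast"), thermo_params(4, 10, 10),
#'                          concentrations = c(0, 1, 3, 10, 30, 100),
#'                          n_traces = 30, seed = 1)
#' tidy(pl$fit)
#' }
#' @export
titration_pipeline <- function(model, thermo, concentrations, n_traces, seed,
                               photo = photophysics(),
                               criteria = qc_criteria(),
                               spec = NULL, n_boot = 500, dwell_mean = 0.5) {
  if (is.null(spec)) spec <- hmm_spec(model, max_iterations = 30)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, length(concentrations) + 1L)
  idealized <- purrr::map2_dfr(concentrations, sub[-1], function(conc, s) {
    d <- simulate_traces(model, thermo, photo, conc, n_traces, seed = s,
                         dwell_mean = dwell_mean)
    d <- apply_qc(d, criteria)
    if (nrow(d) == 0) return(d)
    d <- compute_fret(d)
    hmm <- fit_hmm(d, spec)
    idealize(d, hmm)
  })
  points <- fraction_classical(idealized, n_boot = n_boot, seed = sub[1])
  fit <- fit_titration(points)
  n_kept <- dplyr::n_distinct(idealized$trace_id)
  structure(list(
    fit = fit,
    points = points,
    qc_pass_rate = n_kept / (n_traces * length(concentrations)),
    n_traces_kept = n_kept
  ), class = "titration_pipeline")
}

#' Dissociation-constant recovery study
#'
#' Repeats [titration_pipeline()] across independent seeded replicates and
#' collects the fitted binding parameters, for assessing how well the full
#' analysis chain recovers a known generating `KI`.
#'
#' @inheritParams titration_pipeline
#' @param n_seeds Number of independent replicates.
#' @param seed Master seed; replicate seeds are derived from it.
#' @param ... Passed on to [titration_pipeline()].
#'
#' @return A tibble with one row per replicate: `replicate`, `K0`, `K2`,
#'   `KI`, `converged`, `qc_pass_rate`.
#' @examples
#' \donttest{
#' rec <- kd_recovery(fret_model("yeast"), thermo_params(4, 10, 10),
#'                    concentrations = c(0, 1, 3, 10, 30, 100),
#'                    n_traces = 20, n_seeds = 2, seed = 1)
#' median(rec$KI)
#' }
#' @export
kd_recovery <- function(model, thermo, concentrations, n_traces, n_seeds,
                        seed, ...) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_seeds)
  purrr::map2_dfr(seq_len(n_seeds), rep_seeds, function(i, s) {
    pl <- titration_pipeline(model, thermo, concentrations, n_traces,
                             seed = s, ...)
    tibble::tibble(
      replicate = i,
      K0 = pl$fit$estimate[["K0"]],
      K2 = pl$fit$estimate[["K2"]],
      KI = pl$fit$estimate[["KI"]],
      converged = pl$fit$converged,
      qc_pass_rate = pl$qc_pass_rate
    )
  })
}
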