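#' Per-frame transition matrix realizing a target equilibrium
#'
#' Builds the discrete-time transition matrix used by the simulator: with
#' per-frame switching probability `p = frame_dt / dwell_mean`, each frame
#' either stays put (probability `1 - p`) or redraws the state from the
#' stationary distribution.  The stationary distribution is therefore
#' exactly the target occupancy for any `p`, and the mean dwell time in
#' state `i` is `dwell_mean / (1 - pi_i)`.
#'
#' @param stationary Target stationary probabilities (sums to 1).
#' @param p Per-frame switching probability in `(0, 1]`.
#' @return A row-stochastic matrix.
#' @keywords internal
state_transition_matrix <- function(stationary, p) {
  stopifnot(abs(sum(stationary) - 1) < 1e-12, p > 0, p <= 1)
  k <- length(stationary)
  (1 - p) * diag(k) + p * matrix(stationary, k, k, byrow = TRUE)
}

#' Simulate a hidden tRNA-state path at equilibrium
#'
#' Realizes the classical/hybrid equilibrium implied by the binding model as
#' a discrete-time three-state Markov chain (states Classical, Hybrid1,
#' Hybrid2), with hybrid occupancy divided between Hybrid1 and Hybrid2 by
#' the model's `hybrid_split`.  Photobleaching truncates the observable part
#' of the path at an exponentially drawn frame.
#'
#' @param model A [fret_model()].
#' @param thermo A [thermo_params()].
#' @param concentration Drug concentration, uM.
#' @param photo A [photophysics()] object.
#' @param dwell_mean Nominal mean dwell time per state, seconds; must exceed
#'   the frame duration.
#' @param seed Optional integer seed fixing all randomness of this call.
#'
#' @return A list of class `state_path` with elements `states` (integer
#'   per-frame state index, 1 = Classical), `bleach_frame` (first dark
#'   frame, `NA` if the fluorophores survive the whole record) and
#'   `frame_dt`.
#' @examples
#' p <- simulate_state_path(fret_model("yeast"), thermo_params(4, 10, 10),
#'                          concentration = 0, seed = 1)
#' table(p$states)
#' @export
simulate_state_path <- function(model, thermo, concentration,
                                photo = photophysics(), dwell_mean = 0.5,
                                seed = NULL) {
  validate_fret_model(model)
  stopifnot(inherits(thermo, "thermo_params"), inherits(photo, "photophysics"))
  if (dwell_mean < photo$frame_dt) {
    stop("dwell_mean must be at least one frame duration", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fc <- predict_fraction_classical(thermo, concentration)
  hs <- attr(model, "hybrid_split")
  pi0 <- c(fc, (1 - fc) * (1 - hs), (1 - fc) * hs)
  trans <- state_transition_matrix(pi0, photo$frame_dt / dwell_mean)
  states <- sim_markov_cpp(photo$n_frames, trans, pi0)
  bleach_time <- rexp(1, rate = 1 / photo$bleach_mean_lifetime)
  bleach_frame <- floor(bleach_time / photo$frame_dt) + 1L
  if (bleach_frame > photo$n_frames) bleach_frame <- NA_integer_
  structure(list(states = states, bleach_frame = bleach_frame,
                 frame_dt = photo$frame_dt),
            class = "state_path")
}

#' Render donor/acceptor intensities for a hidden state path
#'
#' Per frame, a FRET efficiency is drawn from the occupied state's Gaussian
#' and split into acceptor (`total * E`) and donor (`total * (1 - E)`)
#' intensities with additive per-channel noise.  Frames after the
#' photobleach, and frames inside donor-blink intervals, carry
#' background-only noise in both channels.  Truth columns record the
#' generating state and the bleach/blink masks.
#'
#' @param path A `state_path` from [simulate_state_path()].
#' @param model The [fret_model()] used to generate `path` (trusted as-is;
#'   not re-validated, so degenerate widths may be used for testing).
#' @param photo A [photophysics()] object.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `frame`, `donor`, `acceptor`, `state_true`
#'   (`NA` once bleached), `bleached`, `blinked`, and attribute `frame_dt`.
#' @examples
#' pa <- simulate_state_path(fret_model("yeast"), thermo_params(4, 10, 10), 0, seed = 1)
#' tr <- render_trace(pa, fret_model("yeast"), seed = 2)
#' head(tr)
#' @export
render_trace <- function(path, model, photo = photophysics(), seed = NULL) {
  stopifnot(inherits(path, "state_path"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(path$states)
  bleach <- path$bleach_frame
  lit <- if (is.na(bleach)) rep(TRUE, n) else seq_len(n) < bleach

  efficiency <- rnorm(n, mean = model$fret_mean[path$states],
                      sd = model$fret_sd[path$states])

  blinked <- rep(FALSE, n)
  lit_time <- sum(lit) * photo$frame_dt
  n_blinks <- rpois(1, photo$blink_rate * lit_time)
  if (n_blinks > 0) {
    starts <- runif(n_blinks, 0, lit_time)
    durs <- rexp(n_blinks, rate = 1 / photo$blink_mean_duration)
    for (i in seq_len(n_blinks)) {
      f0 <- floor(starts[i] / photo$frame_dt) + 1L
      f1 <- min(floor((starts[i] + durs[i]) / photo$frame_dt) + 1L, sum(lit))
      blinked[f0:f1] <- TRUE
    }
    blinked <- blinked & lit
  }

  dark <- !lit | blinked
  donor <- acceptor <- numeric(n)
  tot <- photo$total_intensity_mean
  donor[!dark] <- tot * (1 - efficiency[!dark]) +
    rnorm(sum(!dark), 0, photo$shot_noise_sd)
  acceptor[!dark] <- tot * efficiency[!dark] +
    rnorm(sum(!dark), 0, photo$shot_noise_sd)
  donor[dark] <- rnorm(sum(dark), 0, photo$background_sd)
  acceptor[dark] <- rnorm(sum(dark), 0, photo$background_sd)

  out <- tibble::tibble(
    frame = seq_len(n),
    donor = donor,
    acceptor = acceptor,
    state_true = ifelse(lit, model$state[path$states], NA_character_),
    bleached = !lit,
    blinked = blinked
  )
  attr(out, "frame_dt") <- photo$frame_dt
  out
}

#' Simulate a set of smFRET traces at one drug concentration
#'
#' @inheritParams simulate_state_path
#' @param n_traces Number of traces to generate.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it (traces consume one common RNG stream sequentially).
#'
#' @return A tibble, one row per frame, with columns `trace_id`,
#'   `concentration`, `frame`, `donor`, `acceptor`, `state_true`,
#'   `bleached`, `blinked`; attributes `frame_dt`, `model`, `seed`.
#' @examples
#' d <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
#'                      concentration = 0, n_traces = 2, seed = 1)
#' dplyr::count(d, trace_id)
#' @export
simulate_traces <- function(model, thermo, photo = photophysics(),
                            concentration, n_traces, seed,
                            dwell_mean = 0.5) {
  stopifnot(n_traces >= 1, concentration >= 0)
  validate_fret_model(model)
  if (dwell_mean < photo$frame_dt) {
    stop("dwell_mean must be at least one frame duration", call. = FALSE)
  }
  set.seed(seed)
  n <- photo$n_frames
  fc <- predict_fraction_classical(thermo, concentration)
  hs <- attr(model, "hybrid_split")
  pi0 <- c(fc, (1 - fc) * (1 - hs), (1 - fc) * hs)
  trans <- state_transition_matrix(pi0, photo$frame_dt / dwell_mean)

  # hidden paths, bleach frames and blink masks, trace by trace; the
  # rendering below is vectorized over the whole dataset
  states <- integer(n * n_traces)
  lit <- logical(n * n_traces)
  blinked <- logical(n * n_traces)
  for (i in seq_len(n_traces)) {
    off <- (i - 1L) * n
    states[off + seq_len(n)] <- sim_markov_cpp(n, trans, pi0)
    bleach_time <- rexp(1, rate = 1 / photo$bleach_mean_lifetime)
    bleach <- floor(bleach_time / photo$frame_dt) + 1L
    n_lit <- min(bleach - 1L, n)
    if (n_lit > 0) lit[off + seq_len(n_lit)] <- TRUE
    lit_time <- n_lit * photo$frame_dt
    n_blinks <- rpois(1, photo$blink_rate * lit_time)
    if (n_blinks > 0 && n_lit > 0) {
      starts <- runif(n_blinks, 0, lit_time)
      durs <- rexp(n_blinks, rate = 1 / photo$blink_mean_duration)
      for (b in seq_len(n_blinks)) {
        f0 <- floor(starts[b] / photo$frame_dt) + 1L
        f1 <- min(floor((starts[b] + durs[b]) / photo$frame_dt) + 1L, n_lit)
        blinked[off + (f0:f1)] <- TRUE
      }
    }
  }

  efficiency <- rnorm(n * n_traces, mean = model$fret_mean[states],
                      sd = model$fret_sd[states])
  dark <- !lit | blinked
  tot <- photo$total_intensity_mean
  donor <- acceptor <- numeric(n * n_traces)
  donor[!dark] <- tot * (1 - efficiency[!dark]) +
    rnorm(sum(!dark), 0, photo$shot_noise_sd)
  acceptor[!dark] <- tot * efficiency[!dark] +
    rnorm(sum(!dark), 0, photo$shot_noise_sd)
  donor[dark] <- rnorm(sum(dark), 0, photo$background_sd)
  acceptor[dark] <- rnorm(sum(dark), 0, photo$background_sd)

  out <- tibble::tibble(
    trace_id = rep(sprintf("c%g_t%04d", concentration, seq_len(n_traces)),
                   each = n),
    concentration = concentration,
    frame = rep(seq_len(n), n_traces),
    donor = donor,
    acceptor = acceptor,
    state_true = ifelse(lit, model$state[states], NA_character_),
    bleached = !lit,
    blinked = blinked
  )
  attr(out, "frame_dt") <- photo$frame_dt
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  out
}

#' Simulate a full titration series
#'
#' One trace set per concentration, with per-concentration seeds derived
#' deterministically from the master seed (`set.seed(master)` followed by
#' one `sample.int()` draw per concentration), so the whole titration is
#' reproducible from a single integer.
#'
#' @inheritParams simulate_traces
#' @param concentrations Distinct, non-negative drug concentrations (uM).
#'
#' @return A tibble of all traces, one row per frame, with a
#'   `concentration` column; attribute `dataset_seeds` records the derived
#'   per-concentration seeds.
#' @examples
#' d <- simulate_titration(fret_model("yeast"), thermo_params(4, 10, 10),
#'                         concentrations = c(0, 10), n_traces = 2, seed = 1)
#' dplyr::count(d, concentration)
#' @export
simulate_titration <- function(model, thermo, photo = photophysics(),
                               concentrations, n_traces, seed,
                               dwell_mean = 0.5) {
  if (length(concentrations) == 0) {
    stop("at least one concentration is required", call. = FALSE)
  }
  if (anyDuplicated(concentrations) || any(concentrations < 0)) {
    stop("concentrations must be distinct and non-negative", call. = FALSE)
  }
  set.seed(seed)
  ds_seeds <- sample.int(.Machine$integer.max - 1L, length(concentrations))
  out <- purrr::map2_dfr(concentrations, ds_seeds, function(conc, s) {
    simulate_traces(model, thermo, photo, conc, n_traces, seed = s,
                    dwell_mean = dwell_mean)
  })
  attr(out, "frame_dt") <- photo$frame_dt
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  attr(out, "dataset_seeds") <- ds_seeds
  out
}
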