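#' Compute per-frame FRET efficiency
#'
#' Adds a `fret` column, `E = acceptor / (acceptor + donor)`, computed on
#' pre-bleach frames only.  Frames at or after the detected photobleach are
#' `NA`, as are masked frames whose total intensity falls below
#' `floor_frac` times the trace's mean pre-bleach total (donor blinks and
#' other dark intervals).
#'
#' @param data Trace tibble with `trace_id`, `donor`, `acceptor`.  If a QC
#'   report is attached (see [apply_qc()]) its bleach frames are reused;
#'   otherwise photobleaching is detected per trace.
#' @param floor_frac Fraction of the mean pre-bleach total intensity below
#'   which a frame is masked (default 0.3).
#'
#' @return `data` with an added `fret` column.
#' @examples
#' d <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
#'                      concentration = 0, n_traces = 2, seed = 1)
#' d <- compute_fret(apply_qc(d))
#' range(d$fret, na.rm = TRUE)
#' @export
compute_fret <- function(data, floor_frac = 0.3) {
  stopifnot(all(c("trace_id", "donor", "acceptor") %in% names(data)))
  rep <- attr(data, "qc_report")
  bleach_lookup <- if (!is.null(rep)) {
    setNames(rep$bleach_frame, rep$trace_id)
  } else NULL
  out <- data |>
    dplyr::group_by(.data$trace_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      bleach <- if (!is.null(bleach_lookup) && key$trace_id %in% names(bleach_lookup)) {
        bleach_lookup[[key$trace_id]]
      } else {
        detect_photobleach(df$donor, df$acceptor)$bleach_frame
      }
      total <- df$donor + df$acceptor
      lit <- if (is.na(bleach)) rep(TRUE, n) else seq_len(n) < bleach
      floor_abs <- floor_frac * mean(total[lit])
      ok <- lit & total >= floor_abs & total > 0
      df$fret <- ifelse(ok, df$acceptor / total, NA_real_)
      df
    }) |>
    dplyr::ungroup()
  for (a in c("frame_dt", "model", "qc_report")) attr(out, a) <- attr(data, a)
  out
}

#' Specification of the three-state Gaussian-emission HMM
#'
#' By default the emission means and SDs are fixed at the published
#' per-species state values (the state definitions are treated as known)
#' and only the transition matrix and initial distribution are estimated;
#' set `fix_means`/`fix_sds` to `FALSE` for a free fit.
#'
#' @param model Optional [fret_model()] supplying initial means/SDs and
#'   state labels.
#' @param means,sds Initial (or fixed) emission means and SDs; required
#'   when `model` is `NULL`.
#' @param transition_init Initial row-stochastic transition matrix; default
#'   0.9 on the diagonal, transitions between all states allowed.
#' @param init_probs Initial state distribution; default uniform.
#' @param fix_means,fix_sds Hold emission parameters fixed during EM.
#' @param max_iterations,tolerance Baum-Welch stopping rule: stop when the
#'   log-likelihood improves by less than `tolerance` or after
#'   `max_iterations` iterations.
#' @param sd_floor Lower bound on emission SDs (variance floor 1e-4 by
#'   default), preventing state collapse in free fits.
#'
#' @return A list of class `hmm_spec`.
#' @examples
#' hmm_spec(fret_model("yeast"))
#' @export
hmm_spec <- function(model = NULL, means = NULL, sds = NULL,
                     transition_init = NULL, init_probs = NULL,
                     fix_means = TRUE, fix_sds = TRUE,
                     max_iterations = 100, tolerance = 1e-2,
                     sd_floor = 0.01) {
  if (!is.null(model)) {
    validate_fret_model(model)
    if (is.null(means)) means <- model$fret_mean
    if (is.null(sds)) sds <- model$fret_sd
    labels <- model$state
  } else {
    labels <- paste0("S", seq_along(means))
  }
  k <- length(means)
  stopifnot(k >= 2, length(sds) == k, all(sds > 0),
            !anyDuplicated(means), max_iterations >= 1, tolerance > 0)
  if (is.null(transition_init)) {
    transition_init <- 0.9 * diag(k) + (0.1 / (k - 1)) * (1 - diag(k))
  }
  if (is.null(init_probs)) init_probs <- rep(1 / k, k)
  stopifnot(nrow(transition_init) == k, ncol(transition_init) == k,
            all(abs(rowSums(transition_init) - 1) < 1e-8),
            abs(sum(init_probs) - 1) < 1e-8)
  structure(list(
    n_states = k, means = as.numeric(means), sds = as.numeric(sds),
    transition_init = transition_init, init_probs = as.numeric(init_probs),
    fix_means = fix_means, fix_sds = fix_sds,
    max_iterations = as.integer(max_iterations), tolerance = tolerance,
    sd_floor = sd_floor, state_labels = labels
  ), class = "hmm_spec")
}

# Split a fret-bearing tibble into per-trace series: trailing all-NA tails
# (post-bleach) are dropped, interior NAs (masked frames) are kept and
# marginalized by the HMM recursions.
fret_series_list <- function(data) {
  if (is.list(data) && !is.data.frame(data)) {
    return(lapply(data, as.numeric))
  }
  stopifnot("fret" %in% names(data), "trace_id" %in% names(data))
  sp <- split(data$fret, data$trace_id)
  sp <- lapply(sp, function(x) {
    keep <- which(!is.na(x))
    if (length(keep) == 0) return(NULL)
    x[seq_len(max(keep))]
  })
  sp[!vapply(sp, is.null, logical(1))]
}

#' Fit a Gaussian-emission HMM to a collection of FRET series
#'
#' Baum-Welch expectation-maximization with a transition matrix and initial
#' distribution shared across all traces in the collection.  Transitions
#' between all states are allowed.  The log-likelihood is non-decreasing
#' across iterations; emission SDs are floored at `spec$sd_floor` (the fit
#' is flagged when the floor engages).
#'
#' @param data A tibble with `trace_id` and `fret` columns (see
#'   [compute_fret()]), or a list of numeric FRET series (`NA` = masked).
#' @param spec An [hmm_spec()].
#'
#' @return An object of class `fret_hmm` with elements `means`, `sds`,
#'   `transition`, `init`, `loglik`, `loglik_trace`, `n_iter`, `converged`,
#'   `sd_floored`, `state_labels`.
#' @examples
#' d <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
#'                      concentration = 0, n_traces = 5, seed = 1)
#' d <- compute_fret(apply_qc(d))
#' fit <- fit_hmm(d, hmm_spec(fret_model("yeast")))
#' round(fit$transition, 3)
#' @export
fit_hmm <- function(data, spec) {
  stopifnot(inherits(spec, "hmm_spec"))
  series <- fret_series_list(data)
  if (length(series) == 0) stop("no usable FRET series", call. = FALSE)
  if (any(vapply(series, length, integer(1)) < 2 * spec$n_states)) {
    stop("each series must have at least 2 * n_states frames", call. = FALSE)
  }
  k <- spec$n_states
  means <- spec$means
  sds <- spec$sds
  trans <- spec$transition_init
  init <- spec$init_probs
  ll_trace <- numeric(0)
  converged <- FALSE
  sd_floored <- FALSE
  obs_concat <- unlist(series, use.names = FALSE)
  lengths <- vapply(series, length, integer(1))
  moments <- !spec$fix_means || !spec$fix_sds

  for (iter in seq_len(spec$max_iterations)) {
    acc <- em_accum_cpp(obs_concat, lengths, means, sds, trans, init, moments)
    ll <- acc$loglik
    xi_sum <- acc$xi_sum
    g1 <- acc$g1
    w <- acc$w
    wx <- acc$wx
    wx2 <- acc$wx2
    ll_trace <- c(ll_trace, ll)
    if (iter > 1 && abs(ll - ll_trace[iter - 1]) < spec$tolerance) {
      converged <- TRUE
      break
    }
    rs <- rowSums(xi_sum)
    new_trans <- trans
    pos <- rs > 0
    new_trans[pos, ] <- xi_sum[pos, , drop = FALSE] / rs[pos]
    trans <- new_trans
    init <- g1 / length(series)
    init <- init / sum(init)
    if (!spec$fix_means) means <- wx / pmax(w, 1e-12)
    if (!spec$fix_sds) {
      v <- wx2 / pmax(w, 1e-12) - (wx / pmax(w, 1e-12))^2
      flo <- v < spec$sd_floor^2
      if (any(flo)) sd_floored <- TRUE
      sds <- sqrt(pmax(v, spec$sd_floor^2))
    }
  }

  structure(list(
    means = means, sds = sds, transition = trans, init = init,
    loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
    n_iter = length(ll_trace), converged = converged,
    sd_floored = sd_floored, state_labels = spec$state_labels,
    n_series = length(series)
  ), class = "fret_hmm")
}

#' @export
print.fret_hmm <- function(x, ...) {
  cat(sprintf("<fret_hmm> %d states, %d series, loglik %.2f (%d EM iterations%s)\n",
              length(x$means), x$n_series, x$loglik, x$n_iter,
              if (x$converged) ", converged" else ""))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_hmm
#' @param x A `fret_hmm` object.
#' @param ... Unused.
#' @method tidy fret_hmm
#' @export
tidy.fret_hmm <- function(x, ...) {
  tibble::tibble(
    state = x$state_labels,
    mean = x$means,
    sd = x$sds,
    initial_prob = x$init,
    self_transition = diag(x$transition)
  )
}

#' @rdname fit_hmm
#' @method glance fret_hmm
#' @export
glance.fret_hmm <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    sd_floored = x$sd_floored, n_series = x$n_series
  )
}

#' Forward log-likelihood of FRET series under a fitted HMM
#'
#' @inheritParams fit_hmm
#' @param hmm A `fret_hmm` (or any list with `means`, `sds`, `transition`,
#'   `init`).
#' @return Total log-likelihood over all series.
#' @examples
#' hmm <- list(means = c(0.7, 0.3), sds = c(0.05, 0.05),
#'             transition = matrix(c(.9, .1, .1, .9), 2),
#'             init = c(.5, .5))
#' hmm_loglik(list(c(0.7, 0.68, 0.31)), hmm)
#' @export
hmm_loglik <- function(data, hmm) {
  series <- fret_series_list(data)
  sum(vapply(series, function(s) {
    forward_backward_cpp(s, hmm$means, hmm$sds, hmm$transition, hmm$init)$loglik
  }, numeric(1)))
}

#' Idealize FRET series by the most probable state path
#'
#' Viterbi decoding of each trace under a fitted HMM.  Masked frames
#' (interior `NA`s) are assigned by emission marginalization; post-bleach
#' frames stay `NA`.
#'
#' @inheritParams hmm_loglik
#' @param data A tibble with `trace_id` and `fret` (see [compute_fret()]).
#' @return `data` with an added `state` column (state labels; `NA` on
#'   frames past the end of the usable series).
#' @examples
#' d <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
#'                      concentration = 0, n_traces = 3, seed = 1)
#' d <- compute_fret(apply_qc(d))
#' hmm <- fit_hmm(d, hmm_spec(fret_model("yeast")))
#' d <- idealize(d, hmm)
#' table(d$state, useNA = "ifany")
#' @export
idealize <- function(data, hmm) {
  stopifnot(all(c("trace_id", "fret") %in% names(data)))
  labels <- hmm$state_labels %||% paste0("S", seq_along(hmm$means))
  idx <- split(seq_len(nrow(data)), data$trace_id)
  state <- rep(NA_character_, nrow(data))
  # batch all per-trace series (trimmed at the last unmasked frame) into a
  # single Viterbi call
  rows_list <- lapply(idx, function(ii) {
    keep <- which(!is.na(data$fret[ii]))
    if (length(keep) == 0) integer(0) else ii[seq_len(max(keep))]
  })
  rows <- unlist(rows_list, use.names = FALSE)
  lens <- vapply(rows_list, length, integer(1))
  lens <- lens[lens > 0]
  if (length(rows) > 0) {
    paths <- viterbi_batch_cpp(data$fret[rows], lens, hmm$means, hmm$sds,
                               hmm$transition, hmm$init)
    state[rows] <- labels[paths]
  }
  out <- data
  out$state <- state
  for (a in c("frame_dt", "model", "qc_report")) attr(out, a) <- attr(data, a)
  out
}

#' Dwell segments of an idealized dataset
#'
#' Run-length encodes the per-frame state assignments into dwell segments;
#' segments exactly tile the assigned frame range of each trace.
#'
#' @param data An idealized tibble (see [idealize()]).
#' @return A tibble with `trace_id`, `state`, `start_frame`, `n_frames`.
#' @examples
#' d <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
#'                      concentration = 0, n_traces = 2, seed = 1)
#' d <- idealize(compute_fret(apply_qc(d)), fit_hmm(compute_fret(apply_qc(d)),
#'                                                  hmm_spec(fret_model("yeast"))))
#' dwell_segments(d)
#' @export
dwell_segments <- function(data) {
  stopifnot(all(c("trace_id", "state") %in% names(data)))
  data |>
    dplyr::filter(!is.na(.data$state)) |>
    dplyr::group_by(.data$trace_id) |>
    dplyr::group_modify(function(df, key) {
      r <- rle(df$state)
      ends <- cumsum(r$lengths)
      tibble::tibble(
        state = r$values,
        start_frame = df$frame[c(1L, head(ends, -1) + 1L)],
        n_frames = r$lengths
      )
    }) |>
    dplyr::ungroup()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
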