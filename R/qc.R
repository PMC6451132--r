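#' Trace-selection criteria for smFRET analysis
#'
#' Standard single-molecule trace selection: a single catastrophic
#' photobleaching event, at least 8:1 signal/background-noise and 6:1
#' signal/signal-noise ratios, fewer than four donor blinking events, a
#' donor-acceptor correlation coefficient below 0.5, and at least 50 frames
#' (2 s at 40 ms resolution) spent in any FRET state at or above 0.15.
#'
#' @param max_bleach_events Maximum number of sustained downward
#'   photobleaching steps (default 1: a single catastrophic event).
#' @param min_snr_background Minimum ratio of mean pre-bleach total
#'   intensity to post-bleach background SD.
#' @param min_snr_signal Minimum ratio of mean pre-bleach total intensity
#'   to the (first-difference detrended) pre-bleach signal SD.
#' @param max_blink_events Maximum allowed donor blinking events
#'   (default 3, i.e. strictly fewer than four).
#' @param max_donor_acceptor_corr Exclusive upper bound on the
#'   donor/acceptor correlation coefficient.
#' @param min_state_lifetime_frames Minimum number of pre-bleach frames
#'   with FRET at or above `fret_floor`.
#' @param fret_floor FRET efficiency floor defining "in any FRET state".
#' @param step_k Multiplier on the background noise SD used by the
#'   change-point step detector.
#' @param corr_mode `"raw"` (default) computes the correlation on raw
#'   pre-bleach intensities; `"detrended"` on their first differences.
#'
#' @return A list of class `qc_criteria`.
#' @examples
#' qc_criteria()
#' @export
qc_criteria <- function(max_bleach_events = 1, min_snr_background = 8,
                        min_snr_signal = 6, max_blink_events = 3,
                        max_donor_acceptor_corr = 0.5,
                        min_state_lifetime_frames = 50, fret_floor = 0.15,
                        step_k = 4, corr_mode = c("raw", "detrended")) {
  corr_mode <- match.arg(corr_mode)
  stopifnot(max_bleach_events >= 0, min_snr_background > 0, min_snr_signal > 0,
            max_blink_events >= 0, min_state_lifetime_frames > 0,
            fret_floor > 0, fret_floor < 1, step_k > 0)
  structure(list(
    max_bleach_events = max_bleach_events,
    min_snr_background = min_snr_background,
    min_snr_signal = min_snr_signal,
    max_blink_events = max_blink_events,
    max_donor_acceptor_corr = max_donor_acceptor_corr,
    min_state_lifetime_frames = min_state_lifetime_frames,
    fret_floor = fret_floor,
    step_k = step_k,
    corr_mode = corr_mode
  ), class = "qc_criteria")
}

#' Detect photobleaching on a single trace
#'
#' Change-point detection on total intensity (donor + acceptor): downward
#' mean shifts larger than `k` times the per-frame noise SD (estimated
#' robustly from first differences) are located by binary segmentation.
#' The bleach frame is the first frame of the final sustained drop to
#' background level; `n_bleach_steps` counts sustained downward steps
#' (a drop followed by recovery is a blink, not a bleaching step).
#'
#' @param donor,acceptor Numeric intensity series of equal length (>= 20
#'   frames).
#' @param k Threshold multiplier on the noise SD (default 4).
#' @param min_seg Minimum segment length for the change-point scan.
#'
#' @return A list with `bleach_frame` (first background frame; `NA` when no
#'   bleach is found) and `n_bleach_steps`.
#' @examples
#' d <- c(rep(500, 299), rep(0, 101)); a <- c(rep(500, 299), rep(0, 101))
#' detect_photobleach(d, a)
#' @export
detect_photobleach <- function(donor, acceptor, k = 4, min_seg = 3) {
  stopifnot(length(donor) == length(acceptor))
  total <- donor + acceptor
  n <- length(total)
  if (n < 20) stop("photobleach detection needs at least 20 frames", call. = FALSE)
  # robust per-frame noise SD from first differences; the upper-quantile
  # estimators stay valid when most of the trace is noiseless (the q98
  # fallback covers traces where only a short background tail carries noise)
  adiff <- abs(diff(total))
  sigma <- max(quantile(adiff, 0.90, names = FALSE) / 1.645,
               quantile(adiff, 0.98, names = FALSE) / 2.326) / sqrt(2)
  sigma <- max(sigma, 1e-8, 1e-6 * max(abs(total)))
  steps <- find_steps_cpp(total, k * sigma, min_seg)
  cps <- steps$changepoint
  shifts <- steps$shift
  if (length(cps) == 0) {
    if (mean(total) < k * sigma) {
      stop("trace carries no signal (all-background)", call. = FALSE)
    }
    return(list(bleach_frame = NA_integer_, n_bleach_steps = 0L))
  }
  bounds <- c(1L, cps, n + 1L)
  seg_means <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(total[bounds[i]:(bounds[i + 1L] - 1L)])
  }, numeric(1))
  down <- which(shifts < 0)
  # a sustained step: every later segment stays below the pre-step level
  sustained <- vapply(down, function(j) {
    later <- seg_means[(j + 1L):length(seg_means)]
    all(later < seg_means[j] - k * sigma)
  }, logical(1))
  n_steps <- sum(sustained)
  bg <- seg_means[length(seg_means)]
  bleach <- NA_integer_
  for (j in down) {
    later <- seg_means[(j + 1L):length(seg_means)]
    # final sustained drop: every later segment sits at background level
    # (a blink's recovery segment does not, so blinks are never picked)
    if (all(abs(later - bg) <= k * sigma) && max(later) < seg_means[1] / 2) {
      bleach <- cps[j]
      break
    }
  }
  list(bleach_frame = bleach, n_bleach_steps = as.integer(n_steps))
}

# One trace's metrics as a plain list (assembled into a tibble by
# qc_report); kept free of per-trace tibble construction for speed.
qc_metrics_one <- function(donor, acceptor, criteria) {
  n <- length(donor)
  total <- donor + acceptor
  det <- tryCatch(
    detect_photobleach(donor, acceptor, k = criteria$step_k),
    error = function(e) NULL
  )
  na_row <- list(
    bleach_frame = NA_integer_, n_bleach_steps = NA_integer_,
    snr_background = NA_real_, snr_signal = NA_real_,
    n_blinks = NA_integer_, donor_acceptor_corr = NA_real_,
    frames_above_floor = NA_integer_, fail_reason = NA_character_
  )
  if (is.null(det)) {
    na_row$fail_reason <- "no signal detected"
    return(na_row)
  }
  bleach <- det$bleach_frame
  if (is.na(bleach)) {
    na_row$n_bleach_steps <- det$n_bleach_steps
    na_row$fail_reason <- "no photobleaching event"
    return(na_row)
  }
  if (n - bleach + 1L < 2L) {
    na_row$bleach_frame <- bleach
    na_row$n_bleach_steps <- det$n_bleach_steps
    na_row$fail_reason <- "background undefined (<2 post-bleach frames)"
    return(na_row)
  }
  pre <- seq_len(bleach - 1L)
  post <- bleach:n
  bg_mean <- mean(total[post])
  bg_sd <- sd(total[post])
  blink_thresh <- bg_mean + criteria$step_k * max(bg_sd, 1e-8)
  low <- total[pre] < blink_thresh
  n_blinks <- sum(low[-1] & !low[-length(low)]) + (low[1])
  pre_sig <- pre[!low]
  mean_sig <- mean(total[pre_sig])
  # first-difference detrending removes slow drift from the signal-noise SD
  sig_sd <- if (length(pre_sig) > 2) sd(diff(total[pre_sig])) / sqrt(2) else NA_real_
  corr <- if (criteria$corr_mode == "detrended") {
    suppressWarnings(cor(diff(donor[pre]), diff(acceptor[pre])))
  } else {
    suppressWarnings(cor(donor[pre], acceptor[pre]))
  }
  fret <- acceptor[pre_sig] / total[pre_sig]
  list(
    bleach_frame = bleach,
    n_bleach_steps = det$n_bleach_steps,
    snr_background = mean_sig / max(bg_sd, 1e-12),
    snr_signal = mean_sig / max(sig_sd, 1e-12),
    n_blinks = as.integer(n_blinks),
    donor_acceptor_corr = corr,
    frames_above_floor = sum(fret >= criteria$fret_floor),
    fail_reason = NA_character_
  )
}

#' Per-trace QC metrics and verdicts
#'
#' Computes, for every trace in the dataset, the quantities behind the
#' trace-selection criteria (see [qc_criteria()]) and per-criterion
#' pass/fail flags.
#'
#' @param data A trace tibble with columns `trace_id`, `donor`, `acceptor`
#'   (e.g. from [simulate_traces()] or [simulate_titration()]).
#' @param criteria A [qc_criteria()] object.
#'
#' @return A tibble, one row per trace, with the metrics, logical columns
#'   `ok_*` per criterion, an overall `passed` flag, and `fail_reason`.
#' @examples
#' d <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
#'                      concentration = 0, n_traces = 3, seed = 1)
#' qc_report(d)
#' @export
qc_report <- function(data, criteria = qc_criteria()) {
  stopifnot(inherits(criteria, "qc_criteria"),
            all(c("trace_id", "donor", "acceptor") %in% names(data)))
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  idx <- split(seq_len(nrow(data)), data$trace_id)
  rows <- lapply(idx, function(ii) {
    qc_metrics_one(data$donor[ii], data$acceptor[ii], criteria)
  })
  col <- function(nm, cast) cast(unlist(lapply(rows, `[[`, nm)))
  rep <- tibble::tibble(
    trace_id = names(idx),
    bleach_frame = col("bleach_frame", as.integer),
    n_bleach_steps = col("n_bleach_steps", as.integer),
    snr_background = col("snr_background", as.numeric),
    snr_signal = col("snr_signal", as.numeric),
    n_blinks = col("n_blinks", as.integer),
    donor_acceptor_corr = col("donor_acceptor_corr", as.numeric),
    frames_above_floor = col("frames_above_floor", as.integer),
    fail_reason = col("fail_reason", as.character)
  )
  if ("concentration" %in% names(data)) {
    conc <- vapply(idx, function(ii) data$concentration[ii[1]], numeric(1))
    rep <- dplyr::mutate(rep, concentration = unname(conc),
                         .after = "trace_id")
  }
  rep <- rep |>
    dplyr::mutate(
      ok_bleach = !is.na(.data$bleach_frame) &
        .data$n_bleach_steps <= criteria$max_bleach_events &
        .data$n_bleach_steps >= 1L,
      ok_snr_background = !is.na(.data$snr_background) &
        .data$snr_background >= criteria$min_snr_background,
      ok_snr_signal = !is.na(.data$snr_signal) &
        .data$snr_signal >= criteria$min_snr_signal,
      ok_blinks = !is.na(.data$n_blinks) &
        .data$n_blinks <= criteria$max_blink_events,
      ok_corr = !is.na(.data$donor_acceptor_corr) &
        .data$donor_acceptor_corr < criteria$max_donor_acceptor_corr,
      ok_lifetime = !is.na(.data$frames_above_floor) &
        .data$frames_above_floor >= criteria$min_state_lifetime_frames,
      passed = .data$ok_bleach & .data$ok_snr_background &
        .data$ok_snr_signal & .data$ok_blinks & .data$ok_corr &
        .data$ok_lifetime
    )
  rep
}

#' Filter a trace dataset by the selection criteria
#'
#' Keeps exactly the traces passing all criteria.  The filter is a pure
#' function of (trace, criteria) and is idempotent; the full QC report is
#' attached as attribute `"qc_report"`.
#'
#' @inheritParams qc_report
#' @return The filtered trace tibble (same columns as `data`) with
#'   attributes `qc_report` and, carried over, `frame_dt`.
#' @examples
#' d <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
#'                      concentration = 0, n_traces = 5, seed = 1)
#' kept <- apply_qc(d)
#' attr(kept, "qc_report")
#' @export
apply_qc <- function(data, criteria = qc_criteria()) {
  rep <- qc_report(data, criteria)
  keep <- rep$trace_id[rep$passed]
  if (length(keep) == 0) {
    warning("no traces passed QC", call. = FALSE)
  }
  out <- dplyr::filter(data, .data$trace_id %in% keep)
  attr(out, "qc_report") <- rep
  attr(out, "frame_dt") <- attr(data, "frame_dt")
  attr(out, "model") <- attr(data, "model")
  out
}
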