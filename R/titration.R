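#' Fraction of classical-state ribosomes per concentration
#'
#' Pools Viterbi-assigned frames across traces within each concentration
#' and reports the fraction assigned to the Classical state, with a
#' bootstrap (over traces) standard error.
#'
#' @param data Idealized tibble with `trace_id`, `concentration`, `state`
#'   (see [idealize()]).
#' @param classical_state Label of the classical state.
#' @param n_boot Bootstrap resamples for the SEM (default 1000).
#' @param seed Optional seed making the bootstrap reproducible.
#'
#' @return A tibble with `concentration`, `fraction_classical`, `sem`,
#'   `n_traces` -- one titration point per concentration.
#' @examples
#' \donttest{
#' d <- simulate_titration(fret_model("yeast"), thermo_params(4, 10, 10),
#'                         concentrations = c(0, 10), n_traces = 10, seed = 1)
#' d <- compute_fret(apply_qc(d))
#' d <- idealize(d, fit_hmm(d, hmm_spec(fret_model("yeast"))))
#' fraction_classical(d, seed = 1)
#' }
#' @export
fraction_classical <- function(data, classical_state = "Classical",
                               n_boot = 1000, seed = NULL) {
  stopifnot(all(c("trace_id", "state") %in% names(data)))
  if (!"concentration" %in% names(data)) data$concentration <- 0
  if (!is.null(seed)) set.seed(seed)
  counts <- data |>
    dplyr::filter(!is.na(.data$state)) |>
    dplyr::group_by(.data$concentration, .data$trace_id) |>
    dplyr::summarise(
      n_classical = sum(.data$state == classical_state),
      n_total = dplyr::n(), .groups = "drop"
    )
  if (nrow(counts) == 0 || sum(counts$n_total) == 0) {
    stop("no assigned frames; cannot form a titration point", call. = FALSE)
  }
  counts |>
    dplyr::group_by(.data$concentration) |>
    dplyr::group_modify(function(df, key) {
      fc <- sum(df$n_classical) / sum(df$n_total)
      nt <- nrow(df)
      sem <- if (nt > 1) {
        idx <- matrix(sample.int(nt, nt * n_boot, replace = TRUE), nt, n_boot)
        fb <- colSums(matrix(df$n_classical[idx], nt, n_boot)) /
          colSums(matrix(df$n_total[idx], nt, n_boot))
        sd(fb)
      } else 0
      tibble::tibble(fraction_classical = fc, sem = sem, n_traces = nt)
    }) |>
    dplyr::ungroup()
}

#' Fit the equilibrium binding isotherm to titration data
#'
#' Weighted nonlinear least squares fit of the four-state binding isotherm
#' (see [predict_fraction_classical()]) to fraction-classical observations,
#' estimating `K0`, `K2` and `KI`.  Parameters are optimized on the log
#' scale (enforcing positivity) by Levenberg-Marquardt with multi-start
#' initialization; weights are `1 / sem^2`, falling back to an unweighted
#' fit when any `sem` is zero or missing.  Standard errors come from the
#' local curvature at the optimum; a parameter whose relative standard
#' error exceeds 1 (typically `K2` when saturation is never approached) is
#' flagged weakly identified rather than silently reported.
#'
#' @param points Tibble with columns `concentration`, `fraction_classical`
#'   and optionally `sem`; at least 4 points spanning at least one decade
#'   of positive concentration and including 0.
#' @param start Optional named list/vector with starting `K0`, `K2`, `KI`.
#' @param n_ki_starts Number of log-spaced `KI` starting values.
#'
#' @return An object of class `titration_fit` with the fitted
#'   [thermo_params()], standard errors, residual sum of squares,
#'   convergence flag and the data.
#' @examples
#' th <- thermo_params(4, 10, 10)
#' pts <- tibble::tibble(concentration = c(0, 1, 3, 10, 30, 100),
#'                       fraction_classical = predict_fraction_classical(th, c(0, 1, 3, 10, 30, 100)),
#'                       sem = 0.01)
#' fit <- fit_titration(pts)
#' tidy(fit)
#' @export
fit_titration <- function(points, start = NULL, n_ki_starts = 5) {
  stopifnot(all(c("concentration", "fraction_classical") %in% names(points)))
  conc <- points$concentration
  obs <- points$fraction_classical
  if (nrow(points) < 4) stop("at least 4 titration points are required", call. = FALSE)
  if (!any(conc == 0)) stop("a drug-free (0 concentration) point is required", call. = FALSE)
  pos <- conc[conc > 0]
  if (length(pos) < 2 || max(pos) / min(pos) < 10) {
    stop("concentrations must span at least one decade", call. = FALSE)
  }
  sem <- points$sem
  weighted <- !is.null(sem) && all(is.finite(sem)) && all(sem > 0)
  w <- if (weighted) 1 / sem^2 else rep(1, length(obs))

  resid_fn <- function(logp) {
    th <- thermo_params(exp(logp[1]), exp(logp[2]), exp(logp[3]))
    sqrt(w) * (obs - predict_fraction_classical(th, conc))
  }

  f0 <- obs[which(conc == 0)[1]]
  k0_start <- min(max(1 / max(f0, 0.02) - 1, 0.05), 100)
  fmax <- obs[which.max(conc)]
  k2_start <- if (fmax < 1 && fmax > 0) min(max(1 / (1 / fmax - 1), 0.1), 100) else 10
  ki_grid <- exp(seq(log(min(pos) / 3), log(max(pos) * 3),
                     length.out = n_ki_starts))
  starts <- expand.grid(K0 = k0_start, K2 = unique(c(k2_start, 10)), KI = ki_grid)
  if (!is.null(start)) {
    starts <- rbind(data.frame(K0 = start[["K0"]], K2 = start[["K2"]],
                               KI = start[["KI"]]), starts)
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = log(as.numeric(starts[i, c("K0", "K2", "KI")])),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) stop("isotherm fit failed from every start", call. = FALSE)

  est <- exp(best$par)
  names(est) <- c("K0", "K2", "KI")
  se_log <- tryCatch({
    covm <- solve(best$hessian) * best$deviance / max(length(obs) - 3, 1)
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) tryCatch({
    # near-singular curvature (a runaway parameter): pseudo-inverse keeps
    # the identifiable directions finite
    covm <- MASS::ginv(best$hessian) * best$deviance / max(length(obs) - 3, 1)
    sqrt(pmax(diag(covm), 0))
  }, error = function(e2) rep(NA_real_, 3)))
  se <- est * se_log
  names(se) <- names(est)
  weak <- is.na(se) | (se / est > 1)

  structure(list(
    thermo = thermo_params(est[["K0"]], est[["K2"]], est[["KI"]]),
    estimate = est,
    std_error = se,
    weakly_identified = weak,
    rss = best$deviance,
    converged = best$info %in% 1:3,
    weighted = weighted,
    n_points = length(obs),
    data = tibble::as_tibble(points)
  ), class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit> %d points, %s, RSS %.4g%s\n",
              x$n_points, if (x$weighted) "weighted" else "unweighted",
              x$rss, if (x$converged) "" else " (NOT converged)"))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_titration
#' @param x A `titration_fit`.
#' @param ... Unused.
#' @method tidy titration_fit
#' @export
tidy.titration_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    std.error = unname(x$std_error),
    weakly_identified = unname(x$weakly_identified)
  )
}

#' @rdname fit_titration
#' @method glance titration_fit
#' @export
glance.titration_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, converged = x$converged, weighted = x$weighted,
    n_points = x$n_points, KI = x$estimate[["KI"]]
  )
}

#' @rdname fit_titration
#' @param object A `titration_fit`.
#' @param newdata Optional tibble (or numeric vector) of concentrations.
#' @export
predict.titration_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) {
    object$data$concentration
  } else if (is.numeric(newdata)) newdata else newdata$concentration
  predict_fraction_classical(object$thermo, conc)
}

#' Plot a fitted titration isotherm
#'
#' Fraction-classical observations with SEM error bars and the fitted
#' isotherm, on a log concentration axis (the drug-free point is drawn at
#' a tenth of the smallest positive concentration, standard practice for
#' titration panels).
#'
#' @param object A `titration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot titration_fit
#' @export
autoplot.titration_fit <- function(object, ...) {
  pts <- object$data
  pos_min <- min(pts$concentration[pts$concentration > 0])
  zero_at <- pos_min / 10
  pts$conc_plot <- ifelse(pts$concentration == 0, zero_at, pts$concentration)
  grid <- exp(seq(log(zero_at), log(max(pts$concentration)), length.out = 200))
  curve <- tibble::tibble(
    conc_plot = grid,
    fraction_classical = predict_fraction_classical(
      object$thermo, ifelse(grid <= zero_at, 0, grid))
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$conc_plot,
                                    y = .data$fraction_classical)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$fraction_classical - .data$sem,
      ymax = .data$fraction_classical + .data$sem)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "drug concentration (uM)", y = "fraction classical",
                  subtitle = sprintf("KI = %.3g uM", object$estimate[["KI"]])) +
    ggplot2::theme_minimal()
}

#' Population FRET histogram
#'
#' Pools per-frame FRET efficiencies across traces (per concentration when
#' a `concentration` column is present), bins them on `[-0.1, 1.1]` and
#' normalizes each histogram to unit area, ready for stacked titration
#' panels.
#'
#' @param data Tibble with a `fret` column (see [compute_fret()]).
#' @param binwidth Bin width in FRET units (default 0.03).
#' @return A tibble of class `fret_histogram` with `concentration`,
#'   `bin_mid`, `density`.
#' @examples
#' d <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
#'                      concentration = 0, n_traces = 3, seed = 1)
#' h <- population_histogram(compute_fret(apply_qc(d)))
#' sum(h$density) * 0.03
#' @export
population_histogram <- function(data, binwidth = 0.03) {
  stopifnot("fret" %in% names(data))
  if (!"concentration" %in% names(data)) data$concentration <- 0
  vals <- dplyr::filter(data, !is.na(.data$fret))
  if (nrow(vals) == 0) stop("no FRET values to histogram", call. = FALSE)
  breaks <- seq(-0.1, 1.1 + binwidth, by = binwidth)
  out <- vals |>
    dplyr::group_by(.data$concentration) |>
    dplyr::group_modify(function(df, key) {
      x <- pmin(pmax(df$fret, -0.1), 1.1)
      h <- hist(x, breaks = breaks, plot = FALSE)
      tibble::tibble(bin_mid = h$mids, density = h$density)
    }) |>
    dplyr::ungroup()
  class(out) <- c("fret_histogram", class(out))
  out
}

#' @rdname population_histogram
#' @param object A `fret_histogram`.
#' @param ... Unused.
#' @method autoplot fret_histogram
#' @export
autoplot.fret_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$density)) +
    ggplot2::geom_col(width = diff(object$bin_mid[1:2]), fill = "grey35") +
    ggplot2::facet_wrap(~concentration, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "FRET efficiency", y = "probability density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom graphics hist
NULL
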