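make_idealized <- function(states_per_trace, concentration = 0) {
  tibble::tibble(
    trace_id = rep(names(states_per_trace),
                   vapply(states_per_trace, length, integer(1))),
    concentration = concentration,
    frame = unlist(lapply(states_per_trace, seq_along)),
    state = unlist(states_per_trace)
  )
}

test_that("an all-classical dataset gives fraction 1 with zero sem", {
  d <- make_idealized(list(t1 = rep("Classical", 50), t2 = rep("Classical", 80)))
  pt <- fraction_classical(d, seed = 1)
  expect_equal(pt$fraction_classical, 1)
  expect_equal(pt$sem, 0)
  expect_equal(pt$n_traces, 2L)
})

test_that("drug-free pooled fraction matches the generating equilibrium", {
  pl_data <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
                             photophysics(), 0, 150, seed = 14)
  d <- compute_fret(apply_qc(pl_data))
  idl <- idealize(d, fit_hmm(d, hmm_spec(fret_model("yeast"))))
  pt <- fraction_classical(idl, seed = 2)
  expect_lt(abs(pt$fraction_classical - 0.2), 3 * pt$sem + 0.02)
})

test_that("the bootstrap sem is reproducible under a seed", {
  d <- make_idealized(list(
    t1 = sample(c("Classical", "Hybrid1"), 60, TRUE),
    t2 = sample(c("Classical", "Hybrid2"), 60, TRUE),
    t3 = rep("Classical", 40)
  ))
  p1 <- fraction_classical(d, seed = 7)
  p2 <- fraction_classical(d, seed = 7)
  expect_identical(p1, p2)
  expect_gt(p1$sem, 0)
})

test_that("fitting exact model-generated points recovers all parameters", {
  th <- thermo_params(4, 10, 10)
  conc <- c(0, 1, 3, 10, 30, 100)
  pts <- tibble::tibble(
    concentration = conc,
    fraction_classical = predict_fraction_classical(th, conc),
    sem = 0.01
  )
  fit <- fit_titration(pts)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimate[["KI"]] - 10) / 10, 1e-4)
  expect_lt(abs(fit$estimate[["K0"]] - 4) / 4, 1e-4)
  expect_lt(abs(fit$estimate[["K2"]] - 10) / 10, 1e-3)
})

test_that("binomial-noise titrations recover KI within 20 percent (median)", {
  th <- thermo_params(4, 10, 10)
  conc <- c(0, 1, 3, 10, 30, 100)
  f_true <- predict_fraction_classical(th, conc)
  n_eff <- 500
  set.seed(314)
  rel_err <- replicate(100, {
    fobs <- rbinom(length(conc), n_eff, f_true) / n_eff
    sem <- sqrt(pmax(fobs * (1 - fobs), 1e-4) / n_eff)
    fit <- fit_titration(tibble::tibble(concentration = conc,
                                        fraction_classical = fobs, sem = sem))
    abs(fit$estimate[["KI"]] - 10) / 10
  })
  expect_lte(median(rel_err), 0.2)
})

test_that("the optimizer attains the brute-force grid optimum", {
  set.seed(2718)
  conc <- c(0, 1, 3, 10, 30, 100)
  k0g <- exp(seq(log(0.3), log(30), length.out = 40))
  k2g <- exp(seq(log(0.3), log(100), length.out = 40))
  kig <- exp(seq(log(0.1), log(300), length.out = 40))
  grid <- expand.grid(K0 = k0g, K2 = k2g, KI = kig)
  for (i in 1:20) {
    th <- thermo_params(exp(runif(1, 0, 2.5)), exp(runif(1, 0, 3)),
                        exp(runif(1, 0, 4)))
    fobs <- predict_fraction_classical(th, conc) + rnorm(6, 0, 0.02)
    fobs <- pmin(pmax(fobs, 0.01), 0.99)
    pts <- tibble::tibble(concentration = conc, fraction_classical = fobs,
                          sem = 0.02)
    fit <- fit_titration(pts)
    x <- outer(1 / grid$KI, conc)
    pred <- (1 + x) / (1 + grid$K0 + x * (1 + 1 / grid$K2))
    rss_grid <- colSums((t(pred) - fobs)^2 / 0.02^2)
    expect_gte(min(rss_grid), fit$rss - 1e-6)
  }
})

test_that("the fit is equivariant under concentration rescaling", {
  th <- thermo_params(4, 10, 10)
  conc <- c(0, 1, 3, 10, 30, 100)
  set.seed(33)
  fobs <- pmin(pmax(
    predict_fraction_classical(th, conc) + rnorm(6, 0, 0.01), 0.01), 0.99)
  pts <- tibble::tibble(concentration = conc, fraction_classical = fobs,
                        sem = 0.01)
  f1 <- fit_titration(pts)
  pts2 <- dplyr::mutate(pts, concentration = concentration * 1000)
  f2 <- fit_titration(pts2)
  expect_equal(f2$estimate[["KI"]] / f1$estimate[["KI"]], 1000,
               tolerance = 1e-3)
  expect_equal(f2$estimate[["K0"]], f1$estimate[["K0"]], tolerance = 1e-3)
  expect_equal(f2$estimate[["K2"]], f1$estimate[["K2"]], tolerance = 1e-2)
})

test_that("under-constrained designs are rejected or flagged", {
  th <- thermo_params(4, 10, 10)
  pts3 <- tibble::tibble(concentration = c(0, 10, 100),
                         fraction_classical = c(0.2, 0.3, 0.6), sem = 0.01)
  expect_error(fit_titration(pts3), "at least 4")
  no_zero <- tibble::tibble(concentration = c(1, 3, 10, 100),
                            fraction_classical = c(0.2, 0.25, 0.3, 0.6),
                            sem = 0.01)
  expect_error(fit_titration(no_zero), "drug-free")
  narrow <- tibble::tibble(concentration = c(0, 10, 20, 30),
                           fraction_classical = c(0.2, 0.3, 0.4, 0.5),
                           sem = 0.01)
  expect_error(fit_titration(narrow), "decade")
  # far-from-saturation design: K2 should be flagged weakly identified
  conc <- c(0, 0.3, 1, 3, 10)
  th_weak <- thermo_params(4, 10, 1000)
  set.seed(9)
  fobs <- pmin(pmax(
    predict_fraction_classical(th_weak, conc) + rnorm(5, 0, 0.005), 0.01), 0.99)
  fw <- fit_titration(tibble::tibble(concentration = conc,
                                     fraction_classical = fobs, sem = 0.005))
  expect_true(fw$weakly_identified[["K2"]] || fw$weakly_identified[["KI"]])
})

test_that("population histograms normalize to unit area and show the states", {
  d1 <- tibble::tibble(trace_id = "t1", concentration = 0,
                       fret = rep(0.5, 200))
  h1 <- population_histogram(d1, binwidth = 0.03)
  expect_equal(sum(h1$density > 0), 1)
  expect_equal(sum(h1$density) * 0.03, 1, tolerance = 1e-12)

  dd <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
                        photophysics(), 0, 60, seed = 8)
  h <- population_histogram(compute_fret(apply_qc(dd)), binwidth = 0.03)
  expect_equal(sum(h$density) * 0.03, 1, tolerance = 1e-12)
  peaks <- h$bin_mid[which(diff(sign(diff(h$density))) == -2) + 1]
  for (mode in c(0.65, 0.40, 0.22)) {
    expect_true(any(abs(peaks - mode) <= 0.05))
  }
  expect_error(population_histogram(dplyr::filter(d1, fret > 1)), "no FRET")
})
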