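test_that("per-frame FRET efficiency is the acceptor fraction", {
  n <- 120
  donor <- c(rep(500, 99), rep(0, n - 99))
  acceptor <- c(rep(500, 99), rep(0, n - 99))
  df <- tibble::tibble(trace_id = "t1", donor = donor, acceptor = acceptor)
  out <- compute_fret(df)
  expect_equal(out$fret[1:98], rep(0.5, 98))
  expect_true(all(is.na(out$fret[100:n])))

  df2 <- tibble::tibble(trace_id = "t1",
                        donor = c(rep(1000, 99), rep(0, 21)),
                        acceptor = rep(0, 120))
  out2 <- compute_fret(df2)
  expect_equal(out2$fret[1:98], rep(0, 98))
})

test_that("a noiseless classical-state yeast trace reads 0.65 exactly", {
  n <- 160
  donor <- c(rep(350, 119), rep(0, n - 119))
  acceptor <- c(rep(650, 119), rep(0, n - 119))
  df <- tibble::tibble(trace_id = "t1", donor = donor, acceptor = acceptor)
  out <- compute_fret(df)
  expect_equal(out$fret[1:118], rep(0.65, 118))
})

test_that("forward log-likelihood matches exhaustive path enumeration", {
  set.seed(55)
  for (i in 1:12) {
    h <- random_hmm(3)
    obs <- rnorm(6, 0.5, 0.25)
    if (i %% 3 == 0) obs[sample(6, 1)] <- NA  # masked frame
    ll <- hmm_loglik(list(obs), h)
    expect_equal(ll, enum_loglik(obs, h$means, h$sds, h$transition, h$init),
                 tolerance = 1e-9)
  }
})

test_that("single-frame likelihood is the log initial mixture density", {
  h <- random_hmm(3)
  obs <- 0.4
  expect_equal(hmm_loglik(list(obs), h),
               log(sum(h$init * dnorm(obs, h$means, h$sds))),
               tolerance = 1e-12)
})

test_that("log-likelihood is additive over duplicated datasets", {
  set.seed(66)
  h <- random_hmm(3)
  obs <- rnorm(40, 0.45, 0.2)
  expect_equal(hmm_loglik(list(obs, obs), h), 2 * hmm_loglik(list(obs), h),
               tolerance = 1e-10)
})

test_that("Viterbi equals the exhaustive most-probable path", {
  set.seed(77)
  for (i in 1:8) {
    h <- random_hmm(3)
    obs <- rnorm(8, 0.5, 0.25)
    df <- tibble::tibble(trace_id = "t1", frame = 1:8, fret = obs)
    hm <- list(means = h$means, sds = h$sds, transition = h$transition,
               init = h$init, state_labels = c("S1", "S2", "S3"))
    got <- idealize(df, hm)$state
    oracle <- enum_viterbi(obs, h$means, h$sds, h$transition, h$init)
    expect_equal(match(got, c("S1", "S2", "S3")), oracle$path)
  }
})

test_that("a series pinned at one state mean idealizes to a constant path", {
  m <- fret_model("yeast")
  spec <- hmm_spec(m)
  hm <- list(means = spec$means, sds = spec$sds,
             transition = spec$transition_init, init = spec$init_probs,
             state_labels = spec$state_labels)
  df <- tibble::tibble(trace_id = "t1", frame = 1:30, fret = rep(0.40, 30))
  expect_equal(unique(idealize(df, hm)$state), "Hybrid1")
})

test_that("Baum-Welch log-likelihood never decreases", {
  d <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
                       photophysics(), 0, 30, seed = 41)
  d <- compute_fret(apply_qc(d))
  fit_fixed <- fit_hmm(d, hmm_spec(fret_model("yeast"), tolerance = 1e-8,
                                   max_iterations = 40))
  expect_true(all(diff(fit_fixed$loglik_trace) > -1e-6))
  fit_free <- fit_hmm(d, hmm_spec(fret_model("yeast"), fix_means = FALSE,
                                  fix_sds = FALSE, tolerance = 1e-8,
                                  max_iterations = 40))
  expect_true(all(diff(fit_free$loglik_trace) > -1e-6))
})

test_that("free-fit EM recovers the generating emission means", {
  d <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
                       photophysics(), 0, 200, seed = 52)
  d <- compute_fret(apply_qc(d))
  fit <- fit_hmm(d, hmm_spec(fret_model("yeast"), fix_means = FALSE,
                             fix_sds = FALSE))
  expect_lt(max(abs(sort(fit$means) - c(0.22, 0.40, 0.65))), 0.02)
})

test_that("surplus states starve on single-state data", {
  set.seed(61)
  series <- lapply(1:30, function(i) rnorm(200, 0.65, 0.05))
  spec <- hmm_spec(means = c(0.65, 0.4, 0.2), sds = c(0.05, 0.05, 0.05),
                   fix_means = FALSE, fix_sds = FALSE)
  fit <- fit_hmm(series, spec)
  df <- tibble::tibble(
    trace_id = rep(sprintf("t%02d", 1:30), each = 200),
    frame = rep(1:200, 30),
    fret = unlist(series)
  )
  st <- idealize(df, fit)$state
  occ <- table(factor(st, levels = fit$state_labels)) / length(st)
  expect_lt(sort(as.numeric(occ))[1] + sort(as.numeric(occ))[2], 0.05)
})

test_that("idealized states recover the generating path at default noise", {
  d <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
                       photophysics(), 0, 100, seed = 71)
  d <- compute_fret(apply_qc(d))
  fit <- fit_hmm(d, hmm_spec(fret_model("yeast")))
  idl <- idealize(d, fit)
  ok <- !is.na(idl$state) & !is.na(idl$state_true)
  acc <- mean(idl$state[ok] == idl$state_true[ok])
  expect_gte(acc, 0.95)
})

test_that("fits are deterministic given data and spec", {
  d <- simulate_traces(fret_model("human"), thermo_params(4, 10, 10),
                       photophysics(), 0, 20, seed = 81)
  d <- compute_fret(apply_qc(d))
  f1 <- fit_hmm(d, hmm_spec(fret_model("human"), fix_means = FALSE))
  f2 <- fit_hmm(d, hmm_spec(fret_model("human"), fix_means = FALSE))
  expect_identical(f1$means, f2$means)
  expect_identical(f1$transition, f2$transition)
})

test_that("dwell segments exactly tile each idealized trace", {
  d <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
                       photophysics(), 0, 10, seed = 91)
  d <- compute_fret(apply_qc(d))
  idl <- idealize(d, fit_hmm(d, hmm_spec(fret_model("yeast"))))
  seg <- dwell_segments(idl)
  per_trace <- tapply(seg$n_frames, seg$trace_id, sum)
  assigned <- tapply(!is.na(idl$state), idl$trace_id, sum)
  expect_equal(as.numeric(per_trace),
               as.numeric(assigned[names(per_trace)]))
  # segments are contiguous: starts follow previous start + length
  for (tid in unique(seg$trace_id)) {
    s <- seg[seg$trace_id == tid, ]
    expect_equal(s$start_frame[-1], head(s$start_frame + s$n_frames, -1))
  }
})
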