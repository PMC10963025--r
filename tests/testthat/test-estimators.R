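test_that("per-stimulus summaries use population moments", {
  cm <- count_matrix(rbind(c(0, 1), c(2, 1)))
  st <- summarize_counts(cm)
  expect_equal(st$mean, c(1, 1))
  expect_equal(st$var, c(1, 0))     # population denominator n
  expect_equal(st$cum, c(1, 2))
  st2 <- summarize_counts(cm, var_denominator = "n-1")
  expect_equal(st2$var, c(2, 0))
  ## identical trains: zero variance
  st3 <- summarize_counts(count_matrix(rbind(c(1, 2), c(1, 2))))
  expect_true(all(st3$var == 0))
  expect_error(summarize_counts(count_matrix(matrix(1L, 1, 2))), "2 trains")
  ## binomial moments at scale
  set.seed(1)
  k <- matrix(rbinom(2e4, 4, 0.5), ncol = 2)
  stb <- summarize_counts(count_matrix(k))
  expect_lt(max(abs(stb$mean - 2)), 0.05)
  expect_lt(max(abs(stb$var - 1)), 0.05)
})

test_that("binomial pmf used in fitting is a proper distribution", {
  for (N in 2:6) {
    for (P in seq(0, 1, by = 0.1)) {
      expect_equal(sum(dbinom(0:N, N, P)), 1, tolerance = 1e-12)
    }
  }
})

test_that("binomial N fitting recovers the generating N and handles edge cases", {
  ## frequencies drawn exactly from the pmf must recover N
  N <- 4; P <- 0.7; n <- 1000
  k <- rep(0:N, times = round(dbinom(0:N, N, P) * n))
  f <- fit_binomial_N(k)
  expect_identical(f$N_int, 4L)
  expect_lt(abs(f$P_hat - P), 0.02)

  ## support violation: max count above every candidate
  expect_error(fit_binomial_N(c(0, 2, 6), n_range = 1:5), "maximum observed")

  ## all-zero counts are indeterminate, not a value
  f0 <- fit_binomial_N(rep(0L, 50))
  expect_true(f0$indeterminate)
  expect_true(is.na(f0$N_int))

  ## joint fitting over two stimuli
  set.seed(2)
  k1 <- rbinom(200, 4, 0.8)
  k2 <- rbinom(200, 4, 0.6)
  fj <- fit_binomial_N(list(k1, k2))
  expect_identical(fj$N_int, 4L)
  expect_length(fj$P_hat, 2)
})

test_that("binomial N recovery succeeds in >= 90% of simulated synapses", {
  ## mirrors the high-release-probability condition used for counting
  ## docking sites (RSDS synapse, first-stimulus counts)
  set.seed(3)
  hits <- 0
  reps <- 20
  for (rep in seq_len(reps)) {
    p <- model_params("RSDS", n_sites = 4, delta = 0.8, rho = 1,
                      p_r = 0.9, r = 0.7, s = 0.35)
    cm <- simulate_trains(p, train_protocol(8, 100, 60), seed = 100 + rep)
    f <- fit_binomial_N(cm$counts[, 1])
    if (!f$indeterminate && f$N_int == 4L) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("variance-mean parabola recovers N exactly on exact points", {
  m <- c(0.4, 1.2, 2.0, 2.8)
  st <- data.frame(mean = m, var = m * (1 - m / 4))
  f <- fit_variance_mean(st)
  expect_equal(f$N_real, 4, tolerance = 1e-10)
  expect_identical(f$N_int, 4L)
  expect_false(f$failed)

  ## deterministic counts degenerate
  f0 <- fit_variance_mean(data.frame(mean = m, var = rep(0, 4)))
  expect_true(f0$failed)
  expect_equal(f0$N_real, max(m))

  expect_error(fit_variance_mean(data.frame(mean = c(1, 1, 1),
                                            var = c(0.1, 0.1, 0.1))),
               "distinct")
})

test_that("variance-mean N on a simulated synapse lands near the truth", {
  p <- model_params("RSDS", n_sites = 4, delta = 0.8, rho = 1,
                    p_r = 0.9, r = 0.7, s = 0.35)
  cm <- simulate_trains(p, train_protocol(8, 100, 5000), seed = 21)
  f <- fit_variance_mean(summarize_counts(cm))
  expect_gt(f$N_real, 3.5)
  expect_lt(f$N_real, 4.5)
})

test_that("the two N estimators agree on high-release-probability data", {
  p <- model_params("RSDS", n_sites = 4, delta = 0.8, rho = 1,
                    p_r = 0.9, r = 0.7, s = 0.35)
  cm <- simulate_trains(p, train_protocol(8, 100, 5000), seed = 22)
  nb <- fit_binomial_N(list(cm$counts[, 1], cm$counts[, 2]))
  nv <- fit_variance_mean(summarize_counts(cm))
  expect_identical(nb$N_int, nv$N_int)
})

test_that("estimated N is invariant to the release-probability regime", {
  ## same synapse observed in three conditions; N must not change
  set.seed(23)
  ns <- vapply(c("control", "4AP", "PTP"), function(cn) {
    cm <- simulate_trains(condition_params(cn), train_protocol(8, 100, 3000),
                          seed = match(cn, c("control", "4AP", "PTP")) + 30)
    fit_binomial_N(list(cm$counts[, 1], cm$counts[, 2]))$N_int
  }, integer(1))
  expect_true(all(ns == 4L))
})

test_that("covariance profile matches hand computation and the oracle", {
  ## constant counts: all zero
  cm0 <- count_matrix(matrix(2L, 4, 3))
  expect_true(all(covariance_profile(cm0)$cov == 0))
  ## two trains (1,0) and (0,1): population covariance -0.25
  cm1 <- count_matrix(rbind(c(1, 0), c(0, 1)))
  expect_equal(covariance_profile(cm1)$cov, -0.25)
  expect_error(covariance_profile(count_matrix(matrix(1L, 1, 3))),
               "2 trains")

  ## exhaustive oracle, N = 1, 3 stimuli
  dist <- enumerate_site("RSDS", 0.65, 1, 0.6, 0.7, 0.35, 3)
  cv_exact <- enum_covariance(dist)
  p <- model_params("RSDS", n_sites = 1, delta = 0.65, rho = 1,
                    p_r = 0.6, r = 0.7, s = 0.35)
  cm <- simulate_trains(p, train_protocol(3, 100, 1e5), seed = 24)
  cv <- covariance_profile(cm)$cov
  S <- t(apply(cm$counts, 1, cumsum))
  for (i in 1:2) {
    expect_lt(abs(cv[i] - cv_exact[i]),
              3 * cov_se(S[, i], cm$counts[, i + 1]))
  }
})

test_that("pure depletion gives non-positive covariance in expectation", {
  for (kind in c("RSDS", "LSTS")) {
    p <- model_params(kind, n_sites = 2, delta = 0.7, rho = 0.9,
                      p_r = 0.6, r = 0.7, s = 0)
    cm <- simulate_trains(p, train_protocol(6, 100, 2e4), seed = 25)
    cv <- covariance_profile(cm)
    S <- t(apply(cm$counts, 1, cumsum))
    for (i in seq_len(nrow(cv))) {
      se <- cov_se(S[, i], cm$counts[, i + 1])
      expect_lt(cv$cov[i], 3 * se)
    }
  }
})

test_that("back-extrapolation handles limiting cases exactly", {
  prot <- train_protocol(8, 100, 10)
  ## constant release: cumulative exactly linear, intercept = c
  expect_equal(smn_backextrapolate(cumsum(rep(0.5, 8)), prot)$P_back, 0.5)
  ## full-pool limit: counts (1, 1, 0, ...) per site
  s <- c(1, 1, rep(0, 6))
  fit <- smn_backextrapolate(cumsum(s), prot)
  expect_equal(fit$P_back, 2)
  expect_equal(fit$slope_per_ap, 0)
  expect_error(smn_backextrapolate(cumsum(s), prot, fit_range = 8), ">= 2")
})

test_that("back-extrapolation underestimates the initial pool on simulations", {
  ## documented property: P_back <= rho + delta per site
  for (cn in c("control", "4AP", "PTP")) {
    p <- condition_params(cn)
    cm <- simulate_trains(p, train_protocol(8, 100, 5000),
                          seed = 40 + match(cn, c("control", "4AP", "PTP")))
    st <- summarize_counts(cm)
    fit <- smn_backextrapolate(st$cum / p$n_sites, cm$protocol)
    expect_lt(fit$P_back, p$rho + p$delta + 0.05)
  }
})

test_that("depression metrics cover ratio, decay and degenerate inputs", {
  prot200 <- train_protocol(8, 200, 20)
  ## tau of 1.66 intervals at 200 Hz converts to 8.3 ms
  st <- data.frame(i = 1:8, mean = c(1, 0.95, exp(-((3:8) - 2) / 1.66)))
  dm <- depression_metrics(st, prot200)
  expect_equal(dm$decay_tau_intervals, 1.66, tolerance = 1e-6)
  expect_equal(dm$decay_tau_ms, 8.3, tolerance = 1e-6)
  expect_equal(dm$ppr, 0.95)

  ## exact geometric decay with tau = 1 interval
  st1 <- data.frame(i = 1:8, mean = c(1, 1, 0.8 * exp(-((3:8) - 3) / 1)))
  expect_equal(depression_metrics(st1, prot200)$decay_tau_intervals, 1,
               tolerance = 1e-6)

  ## constant response: no depression, tau non-finite
  stc <- data.frame(i = 1:8, mean = rep(0.4, 8))
  dmc <- depression_metrics(stc, prot200)
  expect_equal(dmc$ppr, 1)
  expect_equal(dmc$depression_ratio, 1, tolerance = 1e-8)
  expect_true(dmc$no_decay)
  expect_false(is.finite(dmc$decay_tau_intervals))

  ## zero first response flags everything undefined
  st0 <- data.frame(i = 1:4, mean = c(0, 1, 1, 1))
  expect_true(depression_metrics(st0, prot200)$undefined)
})

test_that("synchronous/asynchronous classification follows the 5-ms window", {
  prot <- train_protocol(2, 100, 3)
  r <- event_raster(c(1, 1, 2), c(1, 2, 1), c(0.5, 7, 5.0), protocol = prot)
  cls <- classify_sync_async(r)
  expect_equal(cls$synchronous, c(TRUE, FALSE, TRUE))
  expect_error(event_raster(1, 1, -0.1), "non-negative")

  ## mixture generator tail mass: asynchronous fraction matches the
  ## analytic value of the truncated mixture
  lm5 <- latency_model(slow_fraction_by_stimulus = rep(0.3, 8))
  p <- model_params("RSDS", n_sites = 4, delta = 0.9, rho = 1,
                    p_r = 0.9, r = 0.7, s = 0.35)
  d <- generate_condition_dataset(p, train_protocol(8, 100, 400),
                                  latency = lm5, seed = 26)
  cls <- classify_sync_async(d$raster)
  p_async <- mean(!cls$synchronous)
  expected <- async_tail_mass(lm5, 0.3, 5, 10)
  se <- sqrt(expected * (1 - expected) / nrow(cls))
  expect_lt(abs(p_async - expected), 4 * se)
})

test_that("two-step ratio and replenishment arithmetic reproduce the worked chain", {
  expect_equal(round(two_step_ratio(0.2, 5, 4), 2), 0.14)
  expect_equal(two_step_ratio(0.2, 1e9, 4), 0.2)
  expect_equal(two_step_ratio(0.2, 0, 4), 0)
  expect_error(two_step_ratio(0.2, 5, -1), "positive")

  b <- replenishment_breakdown(0.460, 0.097)
  rc <- replenishment_contribution(b, P1 = 0.88, P2 = 0.67)
  expect_equal(round(rc$p2_share, 2), 0.03)
  expect_equal(round(rc$percent_of_sum, 1), 1.3)

  b0 <- replenishment_breakdown(0.5, 0)
  rc0 <- replenishment_contribution(b0, 0.88, 0.67)
  expect_equal(rc0$p2_share, 0)
  expect_equal(rc0$percent_of_sum, 0)
  expect_error(replenishment_contribution(
    replenishment_breakdown(0, 0), 0.5, 0.5), "undefined")
  expect_error(replenishment_breakdown(0.3, 0.4), "exceed")
})
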