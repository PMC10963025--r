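test_that("parameter constructors validate their inputs", {
  expect_error(model_params("RSDS", delta = 1.2), "probability")
  expect_error(model_params("RSDS", n_sites = 0), "integer")
  expect_error(train_protocol(0, 100, 10), "integer")
  expect_error(train_protocol(8, -5, 10), "positive")
  expect_error(ip_params(r_ip = 2), "probability")
  expect_equal(interval_ms(train_protocol(8, 200, 1)), 5)
  expect_equal(rate_to_interval_prob(0, 10), 0)
  expect_lt(abs(rate_to_interval_prob(0.1, 10) - (1 - exp(-1))), 1e-12)
})

test_that("fully primed deterministic limits release 2 (RSDS) and 1 (LSTS) per site", {
  for (N in c(1, 4)) {
    p <- model_params("RSDS", n_sites = N, delta = 1, rho = 1,
                      p_r = 1, r = 1, s = 0)
    cm <- simulate_trains(p, train_protocol(2, 100, 5), seed = 1)
    expect_true(all(cm$counts[, 1] == N))
    expect_true(all(cm$counts[, 2] == N))
  }
  expect_identical(max_rrp_per_site("RSDS"), 2L)
  expect_identical(max_rrp_per_site("LSTS"), 1L)
  ## only the docked vesicle exists when the distal site starts empty
  p <- model_params("RSDS", n_sites = 1, delta = 1, rho = 0,
                    p_r = 1, r = 1, s = 0)
  cm <- simulate_trains(p, train_protocol(8, 100, 5), seed = 1)
  expect_true(all(rowSums(cm$counts) == 1))
})

test_that("no fusion is possible when p_r = 0", {
  p <- model_params("RSDS", n_sites = 3, delta = 1, rho = 1,
                    p_r = 0, r = 1, s = 1)
  cm <- simulate_trains(p, train_protocol(8, 100, 20), seed = 2)
  expect_true(all(cm$counts == 0))
})

test_that("closed-form first- and second-stimulus probabilities match quotes and simulation", {
  p <- model_params("RSDS", n_sites = 1, delta = 0.65, rho = 1,
                    p_r = 0.6, r = 0.7, s = 0.35)
  expect_equal(analytic_P1(p), 0.39)
  expect_equal(analytic_P1(model_params("RSDS", delta = 1, p_r = 1)), 1)
  expect_equal(analytic_P1(model_params("RSDS", delta = 0, p_r = 0.8)), 0)

  p2 <- analytic_P2_rsds(p)
  expect_equal(round(p2$exact, 3), 0.467)
  expect_equal(p2$approx, 1 * 0.7 * 0.6)
  expect_equal(analytic_P2_rsds(model_params("RSDS", delta = 1, rho = 1,
                                             p_r = 1, r = 1))$exact, 1)
  expect_equal(analytic_P2_rsds(model_params("RSDS", delta = 1, rho = 0,
                                             p_r = 1, r = 1))$exact, 0)
  expect_error(analytic_P2_rsds(model_params("LSTS")), "RSDS")

  cm <- simulate_trains(p, train_protocol(2, 100, 1e5), seed = 3)
  se1 <- mc_se(cm$counts[, 1])
  se2 <- mc_se(cm$counts[, 2])
  expect_lt(abs(mean(cm$counts[, 1]) - 0.39), 3 * se1)
  expect_lt(abs(mean(cm$counts[, 2]) - p2$exact), 3 * se2)
})

test_that("conservation and single-stimulus bounds hold without replenishment", {
  for (kind in c("RSDS", "LSTS")) {
    p <- model_params(kind, n_sites = 3, delta = 0.8, rho = 0.9,
                      p_r = 0.7, r = 0.6, s = 0)
    cm <- simulate_trains(p, train_protocol(8, 100, 500), seed = 4)
    cap <- if (kind == "RSDS") 2 else 1
    expect_true(all(rowSums(cm$counts) <= cap * p$n_sites))
    expect_true(all(cm$counts <= p$n_sites))
  }
})

test_that("mean first-stimulus release is monotone in delta and p_r", {
  base <- list(rho = 1, r = 0.5, s = 0.2)
  m_of <- function(delta, p_r) {
    p <- model_params("RSDS", n_sites = 1, delta = delta, rho = base$rho,
                      p_r = p_r, r = base$r, s = base$s)
    analytic_mean_si(p, 1)
  }
  grid <- seq(0.1, 0.9, by = 0.2)
  for (pr in grid) {
    expect_true(all(diff(vapply(grid, m_of, numeric(1), p_r = pr)) >= 0))
  }
  for (de in grid) {
    expect_true(all(diff(vapply(grid, function(pr) m_of(de, pr),
                                numeric(1))) >= 0))
  }
})

test_that("a sealed intermediate pool caps cumulative replenishment", {
  ## with r_ip = 0 the pool is never refilled: total release cannot
  ## exceed the initial RRP content plus the initial pool size
  p <- model_params("RSDS", n_sites = 4, delta = 1, rho = 1,
                    p_r = 1, r = 1, s = 1)
  ip <- ip_params(ip_size0 = 3, r_ip = 0, couple_s_to_ip = TRUE)
  cm <- simulate_trains(p, train_protocol(30, 100, 200), ip = ip, seed = 5)
  expect_true(all(rowSums(cm$counts) <= 2 * 4 + 3))
  expect_gt(max(rowSums(cm$counts)), 8)  # some replenishment does occur
})

test_that("simulation is reproducible bit-for-bit for a given seed", {
  p <- condition_params("4AP")
  a <- simulate_trains(p, train_protocol(8, 100, 100), seed = 7)
  b <- simulate_trains(p, train_protocol(8, 100, 100), seed = 7)
  expect_identical(a$counts, b$counts)
  ## and the global RNG state is left untouched
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(simulate_trains(p, train_protocol(2, 100, 5),
                                           seed = 9)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("scheduling variants agree at the first stimulus and differ later", {
  p <- model_params("RSDS", n_sites = 1, delta = 0.2, rho = 0.3,
                    p_r = 0.9, r = 0.9, s = 0.9)
  ms <- lapply(c("blocked", "chained", "split_interval"), function(sch) {
    cm <- simulate_trains(p, train_protocol(4, 100, 3e4), seed = 11,
                          scheduling = sch)
    colMeans(cm$counts)
  })
  ## stimulus 1 precedes any intra-interval scheduling choice
  expect_lt(abs(ms[[1]][1] - ms[[2]][1]), 0.02)
  expect_lt(abs(ms[[1]][1] - ms[[3]][1]), 0.02)
  ## chaining lets replenished vesicles advance, raising later output
  expect_gt(ms[[2]][2], ms[[1]][2] + 0.01)
})

test_that("replacement-site occupancy diagnostic matches a tracked simulation", {
  p <- condition_params("PTP", n_sites = 1)
  occ <- rs_occupancy_before_stim2(p, "blocked")
  ## independent check by direct probability arithmetic
  ds_empty <- 1 - p$delta * (1 - p$p_r)
  moved <- ds_empty * p$r
  expect_equal(occ$rho2_total, (1 - moved) + moved * p$s)
  expect_equal(occ$rho2_replenishment, moved * p$s)
})

test_that("event simulation attaches fast latencies to released vesicles", {
  p <- model_params("RSDS", n_sites = 1, delta = 1, rho = 1,
                    p_r = 1, r = 1, s = 0)
  prot <- train_protocol(2, 100, 50)
  ## near-delta latency: tiny time constant with an onset delay
  lm0 <- latency_model(tau_fast_ms = 1e-6, tau_slow_ms = 1,
                       onset_delay_ms = 0.5)
  ev <- simulate_events(p, prot, lm0, seed = 13)
  expect_equal(nrow(ev$raster), sum(ev$counts$counts))
  expect_true(all(abs(ev$raster$latency_ms - 0.5) < 1e-3))
  t_abs <- event_times_ms(ev$raster)
  expect_true(all(abs(t_abs - (ev$raster$stimulus - 1) * 10 - 0.5) < 1e-3))

  ## moment check: stimulus-1 latencies average to tau_fast
  lm1 <- latency_model(tau_fast_ms = 0.47, tau_slow_ms = 4)
  ev1 <- simulate_events(p, train_protocol(1, 100, 4000), lm1, seed = 14)
  lat <- ev1$raster$latency_ms
  expect_lt(abs(mean(lat) - 0.47), 3 * mc_se(lat))

  ## empty case
  ev0 <- simulate_events(model_params("RSDS", p_r = 0), prot, lm1,
                         seed = 15)
  expect_identical(nrow(ev0$raster), 0L)
})

test_that("exhaustive enumeration matches simulated means for both models", {
  for (kind in c("RSDS", "LSTS")) {
    dist <- enumerate_site(kind, 0.65, 0.9, 0.6, 0.7, 0.35, 3)
    m_exact <- enum_means(dist)
    p <- model_params(kind, n_sites = 1, delta = 0.65, rho = 0.9,
                      p_r = 0.6, r = 0.7, s = 0.35)
    cm <- simulate_trains(p, train_protocol(3, 100, 4e4), seed = 17)
    for (i in 1:3) {
      expect_lt(abs(mean(cm$counts[, i]) - m_exact[i]),
                3 * mc_se(cm$counts[, i]))
    }
    ## the analytic recursion agrees with the enumeration exactly
    expect_equal(analytic_mean_si(p, 3), m_exact, tolerance = 1e-10)
  }
})
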