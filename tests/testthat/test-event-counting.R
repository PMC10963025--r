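test_that("detection finds isolated events exactly and rejects bad traces", {
  prot <- train_protocol(2, 100, 1)
  tm <- trace_model(noise_sd_pa = 0)

  ## noise-free single template instance: one event at the true time
  r1 <- event_raster(1, 1, 1.0, "fast", prot)
  tr1 <- synthesize_trace(r1, tm)
  ev1 <- detect_events(tr1, tm)
  expect_identical(nrow(ev1), 1L)
  dt <- 1 / tm$sample_khz
  expect_lt(abs(ev1$time_ms - 1.0), 2 * dt)
  expect_lt(abs(ev1$amplitude - 1), 0.05)

  ## flat zero trace: no events
  flat <- tr1
  flat$current_pa <- 0 * flat$current_pa
  expect_identical(nrow(detect_events(flat, tm)), 0L)

  ## non-finite samples rejected
  bad <- tr1
  bad$current_pa[10] <- NA
  expect_error(detect_events(bad, tm), "non-finite")
})

test_that("three closely spaced events are all recovered", {
  prot <- train_protocol(1, 100, 1)
  tm <- trace_model(noise_sd_pa = 0)
  r <- event_raster(rep(1, 3), rep(1, 3), c(0.0, 0.4, 3.0),
                    rep("fast", 3), prot)
  tr <- synthesize_trace(r, tm, duration_ms = 40)
  ev <- split_large_events(detect_events(tr, tm))
  expect_identical(nrow(ev), 3L)
  for (t0 in c(0.0, 0.4, 3.0)) {
    expect_true(any(abs(ev$time_ms - t0) < 0.3))
  }
})

test_that("the split rule doubles oversized events at the stated threshold", {
  mk <- function(a) {
    structure(data.frame(time_ms = 1, amplitude = a,
                         corrected_amplitude = a, split = FALSE),
              class = c("detected_events", "data.frame"))
  }
  expect_identical(nrow(split_large_events(mk(1.69))), 1L)
  s <- split_large_events(mk(1.8))
  expect_identical(nrow(s), 2L)
  expect_true(all(s$split))
  expect_equal(attr(s, "split_percent"), 100)

  ## two coincident unit events merge to amplitude ~2 and are split back
  prot <- train_protocol(1, 100, 1)
  tm <- trace_model(noise_sd_pa = 0, depress_frac = 0)
  r <- event_raster(c(1, 1), c(1, 1), c(0.5, 0.5), rep("fast", 2), prot)
  tr <- synthesize_trace(r, tm, duration_ms = 30)
  ev <- split_large_events(detect_events(tr, tm))
  expect_identical(nrow(ev), 2L)
})

test_that("per-stimulus counting windows events correctly", {
  prot <- train_protocol(2, 100, 1)
  mk <- function(t) {
    structure(data.frame(time_ms = t, amplitude = 1,
                         corrected_amplitude = 1, split = FALSE),
              class = c("detected_events", "data.frame"))
  }
  ## events at 1.2 and 4.9 ms after stimulus 1: s_1 = 2
  cm <- count_per_stimulus(mk(c(1.2, 4.9)), prot)
  expect_equal(unname(cm$counts[1, ]), c(2L, 0L))
  expect_equal(attr(cm, "async_counts"), 0L)
  ## event at 5.1 ms: asynchronous, not in s_1
  cm2 <- count_per_stimulus(mk(5.1), prot)
  expect_equal(unname(cm2$counts[1, ]), c(0L, 0L))
  expect_equal(attr(cm2, "async_counts"), 1L)
  ## second-stimulus window
  cm3 <- count_per_stimulus(mk(c(10.4, 14.9, 15.2)), prot)
  expect_equal(unname(cm3$counts[1, ]), c(0L, 2L))
  ## list of trains gives one row each
  cm4 <- count_per_stimulus(list(mk(1), mk(c(1, 11))), prot)
  expect_equal(dim(cm4$counts), c(2L, 2L))
})

test_that("counting is invariant to joint rescaling of trace and template", {
  prot <- train_protocol(2, 100, 1)
  tm <- trace_model(noise_sd_pa = 2)
  d <- generate_condition_dataset(condition_params("control"), prot,
                                  seed = 71)
  tr <- synthesize_trace(d$raster, tm, seed = 72)
  ev_a <- detect_events(tr, tm)

  tm2 <- tm
  tm2$peak_pa <- tm$peak_pa * 3.7
  tr2 <- tr
  tr2$current_pa <- tr$current_pa * 3.7
  ev_b <- detect_events(tr2, tm2)
  expect_equal(ev_a$time_ms, ev_b$time_ms)
  expect_equal(ev_a$amplitude, ev_b$amplitude, tolerance = 1e-8)
})

test_that("round-trip recovery meets the stated fidelity at control-like rates", {
  ## counts -> raster -> trace -> detection -> counts, noise at 6 % of
  ## the template peak; >= 95 % of events recovered, <= 2 % spurious
  prot <- train_protocol(8, 100, 1)
  tm <- trace_model(noise_sd_pa = 3)
  tot_true <- 0; tot_hit <- 0; tot_fp <- 0
  for (seed in 1:12) {
    d <- generate_condition_dataset(condition_params("control"), prot,
                                    seed = seed)
    if (nrow(d$raster) == 0) next
    tr <- synthesize_trace(d$raster, tm, seed = 1000 + seed)
    ev <- split_large_events(detect_events(tr, tm))
    truth <- attr(tr, "true_events")$time_ms
    det <- ev$time_ms
    used <- rep(FALSE, length(det))
    for (t0 in truth) {
      j <- which(!used & abs(det - t0) <= 0.6)
      if (length(j)) {
        used[j[1]] <- TRUE
        tot_hit <- tot_hit + 1
      }
    }
    tot_true <- tot_true + length(truth)
    tot_fp <- tot_fp + sum(!used)
  }
  expect_gte(tot_hit / tot_true, 0.95)
  expect_lte(tot_fp / tot_true, 0.02)
})

test_that("split percentage stays moderate under high-rate conditions", {
  ## potentiated 200 Hz-like regime, with the latency spread of the
  ## potassium-channel-block condition it emulates (tau_f = 0.70 ms,
  ## onset delay 0.2 ms): the undercount diagnostic -- the fraction of
  ## detected first-stimulus events that exceed the splitting threshold
  ## -- stays below 15 %
  prot <- train_protocol(8, 200, 1)
  tm <- trace_model(noise_sd_pa = 3)
  lat <- latency_model(tau_fast_ms = 0.70, tau_slow_ms = 4,
                       onset_delay_ms = 0.2)
  n_first <- 0; n_big <- 0
  for (seed in 1:20) {
    d <- generate_condition_dataset(condition_params("PTP"), prot,
                                    latency = lat, seed = 80 + seed)
    if (nrow(d$raster) == 0) next
    tr <- synthesize_trace(d$raster, tm, seed = 2000 + seed)
    ev <- detect_events(tr, tm)
    first <- ev[ev$time_ms <= 5.2, , drop = FALSE]
    n_first <- n_first + nrow(first)
    n_big <- n_big + sum(first$corrected_amplitude >= 1.7)
  }
  expect_gt(n_first, 0)
  expect_lt(n_big / n_first, 0.15)
})
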