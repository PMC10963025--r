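#' Generate a full synthetic condition dataset
#'
#' Produces everything the downstream estimators consume for one
#' experimental condition: a count matrix from the docking-model
#' simulator and an event raster in which every released vesicle carries
#' a latency drawn from the fast/slow biexponential mixture for its
#' stimulus index.  The slow component emulates two-step and late
#' asynchronous release (the discrete model itself has no intra-interval
#' fusion); whenever the slow fraction is positive, events beyond the
#' 5 ms synchronous window occur, as in recorded latency histograms.
#' Latencies are truncated at the inter-stimulus interval so every event
#' stays within its stimulus window.
#'
#' @inheritParams simulate_trains
#' @param latency A [latency_model()].
#' @return A list with `counts` (a `count_matrix`) and `raster` (an
#'   `event_raster` with pathway tags `"fast"`/`"slow"`).
#' @examples
#' d <- generate_condition_dataset(condition_params("control"),
#'                                 train_protocol(8, 100, 50), seed = 7)
#' table(d$raster$pathway)
#' @export
generate_condition_dataset <- function(params, protocol,
                                       latency = latency_model(),
                                       ip = NULL, seed = NULL) {
  stopifnot(inherits(latency, "latency_model"))
  local_seed(seed)
  cm <- simulate_trains(params, protocol, ip = ip)
  k <- cm$counts
  n_ev <- sum(k)
  if (n_ev == 0) {
    return(list(counts = cm, raster = event_raster(protocol = protocol)))
  }
  idx <- which(k > 0, arr.ind = TRUE)
  reps <- k[k > 0]
  train <- rep(idx[, 1], reps)
  stimulus <- rep(idx[, 2], reps)
  slow_frac <- latency$slow_fraction_by_stimulus(stimulus)
  slow <- stats::runif(n_ev) < slow_frac
  lmax <- interval_ms(protocol) - latency$onset_delay_ms
  lat <- latency$onset_delay_ms + ifelse(
    slow,
    rexp_trunc(n_ev, latency$tau_slow_ms, lmax),
    rexp_trunc(n_ev, latency$tau_fast_ms, lmax))
  o <- order(train, stimulus, lat)
  list(counts = cm,
       raster = event_raster(train[o], stimulus[o], lat[o],
                             ifelse(slow, "slow", "fast")[o], protocol))
}

## exponential truncated to [0, upper), by inverse CDF
rexp_trunc <- function(n, tau, upper) {
  u <- stats::runif(n)
  -tau * log(1 - u * (1 - exp(-upper / tau)))
}

#' Probability mass of a latency mixture beyond the synchronous window
#'
#' Closed-form tail mass of the truncated fast/slow mixture beyond
#' `window_ms`, i.e. the expected asynchronous fraction of events at a
#' stimulus with slow-component weight `slow_frac`.  Used to check the
#' generator against [classify_sync_async()].
#'
#' @param latency A [latency_model()].
#' @param slow_frac Slow-component weight at the stimulus of interest.
#' @param window_ms Synchronous window (default 5).
#' @param interval_ms Truncation bound (the inter-stimulus interval).
#' @return Expected asynchronous fraction.
#' @export
async_tail_mass <- function(latency, slow_frac, window_ms = 5,
                            interval_ms = 10) {
  tail_one <- function(tau) {
    upper <- interval_ms - latency$onset_delay_ms
    w <- window_ms - latency$onset_delay_ms
    if (w <= 0) return(1)
    if (w >= upper) return(0)
    (exp(-w / tau) - exp(-upper / tau)) / (1 - exp(-upper / tau))
  }
  slow_frac * tail_one(latency$tau_slow_ms) +
    (1 - slow_frac) * tail_one(latency$tau_fast_ms)
}

#' Postsynaptic current trace model
#'
#' A miniature-EPSC template described by a triple-exponential with five
#' parameters -- rise time, peak amplitude, fast decay, slow decay, and
#' the amplitude fraction of the slow decay -- plus the acquisition and
#' noise settings used when synthesising traces.  Closely spaced events
#' are depressed multiplicatively (receptor saturation/desensitisation)
#' by `1 - depress_frac * exp(-dt / tau_recovery_ms)` relative to the
#' preceding event; the constants are configuration values, not measured
#' quantities.
#'
#' @param rise_ms Template rise time constant, ms.
#' @param peak_pa Peak amplitude, pA (positive; sign conventions are up
#'   to the caller).
#' @param tau_decay_fast_ms,tau_decay_slow_ms Decay time constants, ms.
#' @param slow_decay_frac Amplitude fraction of the slow decay.
#' @param sample_khz Sampling rate, kHz (default 50).
#' @param noise_sd_pa Gaussian noise standard deviation, pA.
#' @param depress_frac,tau_recovery_ms Amplitude-recovery rule constants.
#' @return An object of class `trace_model`.
#' @export
trace_model <- function(rise_ms = 0.15, peak_pa = 50,
                        tau_decay_fast_ms = 1.0, tau_decay_slow_ms = 8.0,
                        slow_decay_frac = 0.3, sample_khz = 50,
                        noise_sd_pa = 0, depress_frac = 0.3,
                        tau_recovery_ms = 5) {
  stopifnot(rise_ms > 0, peak_pa > 0, tau_decay_fast_ms > 0,
            tau_decay_slow_ms > 0, slow_decay_frac >= 0,
            slow_decay_frac <= 1, sample_khz > 0, noise_sd_pa >= 0,
            depress_frac >= 0, depress_frac < 1, tau_recovery_ms > 0)
  structure(as.list(environment()), class = "trace_model")
}

#' Evaluate the mEPSC template
#'
#' @param trace A [trace_model()].
#' @param t_ms Times from event onset, ms.
#' @return Template current in pA (peak equals `peak_pa`).
#' @export
mepsc_template <- function(trace, t_ms) {
  shape <- function(t) {
    ifelse(t < 0, 0,
           (1 - exp(-t / trace$rise_ms)) *
             ((1 - trace$slow_decay_frac) * exp(-t / trace$tau_decay_fast_ms)
              + trace$slow_decay_frac * exp(-t / trace$tau_decay_slow_ms)))
  }
  tg <- seq(0, 5 * trace$tau_decay_slow_ms, by = 1 / trace$sample_khz / 4)
  peak <- max(shape(tg))
  trace$peak_pa * shape(t_ms) / peak
}

#' Synthesise a current trace from an event raster
#'
#' Forward model for the event counter: places one scaled mEPSC template
#' at each release-event time, depresses amplitudes of closely spaced
#' events by the recovery rule of the [trace_model()], and adds white
#' Gaussian noise.
#'
#' @param raster An [event_raster()] for a single train (all rows must
#'   share one train index).
#' @param trace A [trace_model()].
#' @param duration_ms Trace duration (default: train length plus a
#'   40 ms tail).
#' @param seed Optional seed for the noise.
#' @return A data frame of class `synaptic_trace` with columns `time_ms`
#'   and `current_pa`; attributes `trace_model`, `protocol`, and
#'   `true_events` (times and depressed amplitudes, for round-trip
#'   checks).
#' @export
synthesize_trace <- function(raster, trace, duration_ms = NULL,
                             seed = NULL) {
  stopifnot(inherits(raster, "event_raster"), inherits(trace, "trace_model"))
  protocol <- attr(raster, "protocol")
  if (length(unique(raster$train)) > 1) {
    stop("`raster` must contain a single train; split it first",
         call. = FALSE)
  }
  dt <- 1 / trace$sample_khz
  if (dt > trace$rise_ms) {
    stop("sampling interval exceeds the template rise time; raise ",
         "`sample_khz`", call. = FALSE)
  }
  local_seed(seed)
  ev_t <- sort(event_times_ms(raster, protocol))
  if (is.null(duration_ms)) {
    duration_ms <- protocol$n_stim * interval_ms(protocol) + 40
  }
  time <- seq(0, duration_ms, by = dt)
  cur <- numeric(length(time))
  amp <- rep(1, length(ev_t))
  if (length(ev_t) > 1) {
    gaps <- diff(ev_t)
    amp[-1] <- 1 - trace$depress_frac * exp(-gaps / trace$tau_recovery_ms)
  }
  for (k in seq_along(ev_t)) {
    cur <- cur + amp[k] * mepsc_template(trace, time - ev_t[k])
  }
  if (trace$noise_sd_pa > 0) {
    cur <- cur + stats::rnorm(length(cur), 0, trace$noise_sd_pa)
  }
  structure(data.frame(time_ms = time, current_pa = cur),
            class = c("synaptic_trace", "data.frame"),
            trace_model = trace, protocol = protocol,
            true_events = data.frame(time_ms = ev_t, rel_amplitude = amp))
}
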