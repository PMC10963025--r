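#' Classify release events as synchronous or asynchronous
#'
#' Events with a latency of at most `window_ms` after their stimulus are
#' synchronous (docked-vesicle release upon the action potential); later
#' events, up to the next stimulus, are asynchronous (vesicles passing
#' through the docking pathway between stimuli).
#'
#' @param raster An [event_raster()].
#' @param window_ms Synchronous window after each stimulus (default 5).
#' @return The raster with an added logical column `synchronous`.
#' @export
classify_sync_async <- function(raster, window_ms = 5) {
  stopifnot(inherits(raster, "event_raster"))
  if (any(raster$latency_ms < 0)) {
    stop("negative latencies are not allowed", call. = FALSE)
  }
  raster$synchronous <- raster$latency_ms <= window_ms
  raster
}

#' Synchronous count matrix from a classified raster
#'
#' @param raster An [event_raster()] with a `synchronous` column (see
#'   [classify_sync_async()]).
#' @param protocol Protocol; defaults to the raster's own.
#' @param synchronous_only Count only synchronous events (default) or all.
#' @return A [count_matrix()] of per-train, per-stimulus counts.
#' @export
raster_to_counts <- function(raster, protocol = attr(raster, "protocol"),
                             synchronous_only = TRUE) {
  stopifnot(inherits(raster, "event_raster"), !is.null(protocol))
  ev <- raster
  if (synchronous_only) {
    if (is.null(ev$synchronous)) ev <- classify_sync_async(ev)
    ev <- ev[ev$synchronous, , drop = FALSE]
  }
  counts <- matrix(0L, protocol$n_trains, protocol$n_stim)
  if (nrow(ev) > 0) {
    tab <- table(factor(ev$train, levels = seq_len(protocol$n_trains)),
                 factor(ev$stimulus, levels = seq_len(protocol$n_stim)))
    counts <- matrix(as.integer(tab), protocol$n_trains, protocol$n_stim)
  }
  colnames(counts) <- paste0("stim_", seq_len(protocol$n_stim))
  new_count_matrix(counts, protocol)
}

#' Fit a biexponential mixture to release latencies
#'
#' Single-synapse latency histograms are biphasic: a fast component from
#' direct docked-vesicle release and a slow component from two-step
#' release via the replacement site.  This fits the two-exponential
#' mixture density
#' `f(t) = (1 - w) / tau_f * exp(-(t - d) / tau_f) + w / tau_s *
#' exp(-(t - d) / tau_s)` for `t >= d` by maximum likelihood
#' (`objective = "ml"`, default) or by least squares on a binned
#' histogram (`objective = "binned"`, for parity with histogram-based
#' analyses).
#'
#' @param latencies Numeric vector of latencies in ms (>= 100 values
#'   recommended for a stable fit; fewer produce a warning).
#' @param onset_delay_ms Fixed onset delay `d` subtracted before fitting
#'   (default 0); latencies below it are rejected.
#' @param objective `"ml"` or `"binned"`.
#' @param bin_ms Bin width for the binned objective (default 0.2 ms).
#' @return A list of class `latency_fit`: `tau_fast_ms`, `tau_slow_ms`,
#'   `slow_fraction`, `extra_delay_ms`, `degenerate` (TRUE when the two
#'   time constants collapse onto each other), and `logLik` (ML only).
#' @examples
#' set.seed(1)
#' t <- ifelse(runif(2000) < 0.5, rexp(2000, 1 / 0.47), rexp(2000, 1 / 4))
#' fit_latency_biexp(t)
#' @export
fit_latency_biexp <- function(latencies, onset_delay_ms = 0,
                              objective = c("ml", "binned"),
                              bin_ms = 0.2) {
  objective <- match.arg(objective)
  t <- as.numeric(latencies)
  if (length(t) == 0) stop("no latencies supplied", call. = FALSE)
  if (any(t < onset_delay_ms)) {
    stop("latencies below the onset delay are not allowed", call. = FALSE)
  }
  if (length(t) < 100) {
    warning("fewer than 100 latencies; the biexponential fit may be unstable")
  }
  t <- t - onset_delay_ms

  mix_dens <- function(t, tf, ts, w) {
    (1 - w) / tf * exp(-t / tf) + w / ts * exp(-t / ts)
  }
  ## theta = (log tau_f, log tau_s, logit w_slow)
  unpack <- function(theta) {
    list(tf = exp(theta[1]), ts = exp(theta[2]), w = stats::plogis(theta[3]))
  }
  q <- stats::quantile(t, c(0.25, 0.9))
  start <- c(log(max(q[1], 1e-3)), log(max(q[2], 2e-3)), stats::qlogis(0.3))

  if (objective == "ml") {
    nll <- function(theta) {
      p <- unpack(theta)
      -sum(log(pmax(mix_dens(t, p$tf, p$ts, p$w), 1e-300)))
    }
    opt <- stats::optim(start, nll, method = "BFGS",
                        control = list(maxit = 500))
    p <- unpack(opt$par)
    ll <- -opt$value
  } else {
    h <- graphics::hist(t, breaks = seq(0, max(t) + bin_ms, by = bin_ms),
                        plot = FALSE)
    dens <- h$density
    mids <- h$mids
    obj <- function(theta) {
      p <- unpack(theta)
      sum((dens - mix_dens(mids, p$tf, p$ts, p$w))^2)
    }
    opt <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 500))
    p <- unpack(opt$par)
    ll <- NA_real_
  }
  ## order components so tau_fast < tau_slow
  if (p$tf > p$ts) {
    p <- list(tf = p$ts, ts = p$tf, w = 1 - p$w)
  }
  structure(list(tau_fast_ms = p$tf, tau_slow_ms = p$ts,
                 slow_fraction = p$w,
                 extra_delay_ms = onset_delay_ms,
                 degenerate = abs(log(p$ts / p$tf)) < 0.1,
                 logLik = ll),
            class = "latency_fit")
}

#' @export
print.latency_fit <- function(x, ...) {
  cat(sprintf(
    "<latency_fit> tau_f = %.3g ms, tau_s = %.3g ms, slow fraction = %.2f%s\n",
    x$tau_fast_ms, x$tau_slow_ms, x$slow_fraction,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
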