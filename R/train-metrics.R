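#' Back-extrapolation of cumulative release (SMN method)
#'
#' Estimates the readily-releasable-pool size from a train by the
#' Schneggenburger--Meyer--Neher construction applied to vesicle counts:
#' cumulative synchronous release is plotted against time at points
#' placed 5 ms after each stimulus (when the synchronous window has
#' closed), a regression line is fitted through the late, steady-state
#' points, and the line is read back at the first measurement point.
#' The intercept `P_back` estimates the pool content consumed above the
#' steady replenishment; because depletion during a train is incomplete,
#' `P_back` underestimates the true pool size, and the bias shrinks as
#' depression deepens.
#'
#' Units follow the input: per-synapse counts give a per-synapse pool,
#' per-site means give a pool per docking site.
#'
#' @param x A [count_matrix()], a [summarize_counts()] result, or a
#'   numeric vector of per-stimulus mean synchronous counts.
#' @param protocol A [train_protocol()]; taken from `x` when available.
#' @param fit_range Stimulus indices for the regression (default: the
#'   last four, e.g. 5--8 of an 8-stimulus train; strongly depressing
#'   conditions warrant 5--8, weakly depressing ones 6--8).
#' @param window_ms Offset of the measurement points after each stimulus
#'   (default 5 ms).
#' @return A list of class `smn_fit`: `P_back`, `slope_per_ms`,
#'   `slope_per_ap` (steady replenishment per stimulus), `fit_range`,
#'   and `points` (time/cumulative pairs used).
#' @examples
#' p <- condition_params("PTP")
#' cm <- simulate_trains(p, train_protocol(8, 100, 2000), seed = 4)
#' st <- summarize_counts(cm, n_sites = 4)
#' smn_backextrapolate(st$cum / 4, cm$protocol)$P_back
#' @export
smn_backextrapolate <- function(x, protocol = NULL, fit_range = NULL,
                                window_ms = 5) {
  if (inherits(x, "count_matrix")) {
    protocol <- x$protocol
    cum <- summarize_counts(x)$cum
  } else if (inherits(x, "stimulus_stats")) {
    if (is.null(protocol)) protocol <- attr(x, "protocol")
    cum <- x$cum
  } else {
    cum <- as.numeric(x)
  }
  if (is.null(protocol)) {
    stop("a `protocol` is required when `x` carries none", call. = FALSE)
  }
  n <- length(cum)
  if (is.null(fit_range)) fit_range <- max(2, n - 3):n
  fit_range <- as.integer(fit_range)
  if (length(fit_range) < 2 || any(fit_range < 1 | fit_range > n)) {
    stop("`fit_range` must contain >= 2 stimulus indices within the train",
         call. = FALSE)
  }
  dt <- interval_ms(protocol)
  t_meas <- (seq_len(n) - 1) * dt + window_ms
  fit <- stats::lm(y ~ t, data.frame(t = t_meas[fit_range],
                                     y = cum[fit_range]))
  co <- stats::coef(fit)
  p_back <- unname(co[1] + co[2] * t_meas[1])
  structure(list(P_back = p_back,
                 slope_per_ms = unname(co[2]),
                 slope_per_ap = unname(co[2]) * dt,
                 fit_range = range(fit_range),
                 window_ms = window_ms,
                 points = data.frame(time_ms = t_meas, cum = cum)),
            class = "smn_fit")
}

#' Depression metrics of a train response
#'
#' Summarises short-term depression of a train: the paired-pulse ratio
#' `s_2 / s_1`; the depression ratio (steady-state release per stimulus
#' at the end of the train, obtained from the slope of a regression line
#' through the late cumulative points, divided by `s_1`); and the time
#' constant of the exponential fall-off of `s_i` for `i > 2`, fitted
#' with the asymptote fixed at zero.  The fall-off is fitted in stimulus
#' index space and converted to ms with the inter-stimulus interval.
#'
#' @param stats A [summarize_counts()] result (or data frame with
#'   columns `i` and `mean`).
#' @param protocol A [train_protocol()]; taken from `stats` when
#'   available.
#' @param fit_range Stimulus indices for the steady-state regression
#'   (default: last four).
#' @return A list of class `depression_metrics`: `ppr`,
#'   `depression_ratio`, `decay_tau_intervals`, `decay_tau_ms`, and
#'   flags `undefined` (first response zero) and `no_decay` (counts not
#'   decreasing; tau reported as `Inf`).
#' @examples
#' st <- data.frame(i = 1:8,
#'                  mean = c(1, 0.95, exp(-(3:8 - 2) / 1.66)))
#' depression_metrics(st, train_protocol(8, 200, 20))$decay_tau_ms
#' @export
depression_metrics <- function(stats, protocol = NULL, fit_range = NULL) {
  if (is.null(protocol)) protocol <- attr(stats, "protocol")
  if (is.null(protocol)) {
    stop("a `protocol` is required", call. = FALSE)
  }
  m <- stats$mean
  n <- length(m)
  if (n < 2) stop("at least 2 stimuli are needed", call. = FALSE)
  dt <- interval_ms(protocol)
  if (m[1] == 0) {
    return(structure(list(ppr = NA_real_, depression_ratio = NA_real_,
                          decay_tau_intervals = NA_real_,
                          decay_tau_ms = NA_real_,
                          undefined = TRUE, no_decay = FALSE),
                     class = "depression_metrics"))
  }
  ppr <- m[2] / m[1]
  if (is.null(fit_range)) fit_range <- max(2, n - 3):n
  cum <- cumsum(m)
  t_meas <- (seq_len(n) - 1) * dt
  late <- stats::lm(y ~ t, data.frame(t = t_meas[fit_range],
                                      y = cum[fit_range]))
  ss_per_ap <- unname(stats::coef(late)[2]) * dt
  tau <- fit_zero_asymptote_decay(m, first = 3L)
  structure(list(ppr = ppr,
                 depression_ratio = ss_per_ap / m[1],
                 decay_tau_intervals = tau,
                 decay_tau_ms = tau * dt,
                 undefined = FALSE,
                 no_decay = !is.finite(tau)),
            class = "depression_metrics")
}

## Exponential fall-off m_i = A * exp(-(i - first) / tau) for i >= first,
## asymptote fixed at 0.  Log-linear start, then least squares on the
## original scale.  Non-decaying inputs give tau = Inf.
fit_zero_asymptote_decay <- function(m, first = 3L) {
  i <- first:length(m)
  y <- m[i]
  if (length(i) < 2 || all(y == 0)) return(NA_real_)
  pos <- y > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(y[pos]) ~ i[pos])
    slope <- unname(stats::coef(lf)[2])
  } else {
    slope <- -1
  }
  if (slope >= 0) return(Inf)
  start <- list(A = max(y), tau = -1 / slope)
  ## a perfect exponential has zero residuals, which nls reports noisily
  fit <- try(suppressWarnings(
    stats::nls(y ~ A * exp(-(i - first) / tau),
               data.frame(i = i, y = y), start = start,
               control = stats::nls.control(warnOnly = TRUE))),
    silent = TRUE)
  if (inherits(fit, "try-error")) return(-1 / slope)
  tau <- unname(stats::coef(fit)["tau"])
  if (!is.finite(tau) || tau <= 0) -1 / slope else tau
}
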