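#' Per-stimulus summary statistics of a count matrix
#'
#' Computes, for each stimulus index `i`, the mean and variance of the
#' released-vesicle count `s_i` across trains, the mean cumulative count
#' `S_i = s_1 + ... + s_i`, and -- when a docking-site number is supplied
#' -- the per-site release probability `P_i = mean(s_i) / N`.
#'
#' Variances use the population denominator `n` by default, matching the
#' moment definition used for the covariance of release counts; set
#' `var_denominator = "n-1"` for the unbiased sample variance.
#'
#' @param cm A [count_matrix()] (or a bare integer matrix).
#' @param n_sites Optional docking-site number for `P_i`.
#' @param var_denominator `"n"` (population moments, default) or
#'   `"n-1"`.
#' @return A data frame of class `stimulus_stats` with columns `i`,
#'   `mean`, `var`, `cum`, and `P_i` (NA without `n_sites`); attributes
#'   `n_trains`, `protocol`, `n_sites`.
#' @examples
#' cm <- simulate_trains(condition_params("4AP"),
#'                       train_protocol(8, 100, 500), seed = 2)
#' summarize_counts(cm, n_sites = 4)
#' @export
summarize_counts <- function(cm, n_sites = NULL,
                             var_denominator = c("n", "n-1")) {
  var_denominator <- match.arg(var_denominator)
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  protocol <- if (inherits(cm, "count_matrix")) cm$protocol else NULL
  n <- nrow(counts)
  if (n < 2) {
    stop("at least 2 trains are needed to estimate variances",
         call. = FALSE)
  }
  m <- colMeans(counts)
  v <- apply(counts, 2, stats::var) * (n - 1) / n
  if (var_denominator == "n-1") v <- v * n / (n - 1)
  cum <- cumsum(m)
  p <- if (is.null(n_sites)) rep(NA_real_, length(m)) else m / n_sites
  out <- data.frame(i = seq_along(m), mean = m, var = v, cum = cum,
                    P_i = p, row.names = NULL)
  structure(out, class = c("stimulus_stats", "data.frame"),
            n_trains = n, protocol = protocol, n_sites = n_sites,
            var_denominator = var_denominator)
}

#' Covariance profile of cumulative and next-stimulus counts
#'
#' Computes `cov(S_i, s_{i+1})` for `i = 1 .. n_stim - 1`, where `S_i` is
#' the cumulative released count through stimulus `i`.  The covariance
#' uses the population normalisation (division by the number of trains).
#' Depletion of a shared, finite pool makes successive counts
#' anticorrelated, so the profile is negative in expectation for
#' depressing synapses; its shape (notably where the magnitude peaks)
#' discriminates between docking-site models.
#'
#' @param cm A [count_matrix()] or integer matrix with >= 2 trains and
#'   >= 2 stimuli.
#' @return A data frame of class `covariance_profile` with columns `i`
#'   and `cov`; attribute `n_trains`.
#' @examples
#' cm <- simulate_trains(condition_params("4AP"),
#'                       train_protocol(8, 100, 2000), seed = 3)
#' covariance_profile(cm)
#' @export
covariance_profile <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  n <- nrow(counts)
  if (n < 2) stop("at least 2 trains are needed", call. = FALSE)
  if (ncol(counts) < 2) stop("at least 2 stimuli are needed", call. = FALSE)
  S <- t(apply(counts, 1, cumsum))
  idx <- seq_len(ncol(counts) - 1)
  cv <- vapply(idx, function(i) {
    x <- S[, i]
    y <- counts[, i + 1]
    mean((x - mean(x)) * (y - mean(y)))
  }, numeric(1))
  structure(data.frame(i = idx, cov = cv),
            class = c("covariance_profile", "data.frame"), n_trains = n)
}
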