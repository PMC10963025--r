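#' Estimate the docking-site number by binomial fitting
#'
#' Fits the empirical distribution of released-vesicle counts at one (or
#' jointly at several) stimulus with a binomial law
#' `p(k) = choose(N, k) P^k (1 - P)^(N - k)`.  For each candidate integer
#' `N`, the release probability `P` is optimised to minimise the summed
#' squared deviation between the empirical relative frequencies of
#' `k = 0 .. N` and the binomial probabilities; the returned `N` is the
#' candidate with the smallest total error (ties go to the smaller `N`).
#' High-release-probability data constrain `N` best, which is why the
#' joint form over the first two stimuli of a high-`P` condition is the
#' recommended use.
#'
#' A multinomial maximum-likelihood variant is available via
#' `objective = "ml"`; the selected `N` can differ from the
#' squared-deviation fit on small samples.
#'
#' @param counts Integer vector of per-train counts at one stimulus, or a
#'   list of such vectors fitted jointly with a common `N` (each stimulus
#'   keeps its own `P`).
#' @param n_range Candidate `N` values (default `1:10`).  Candidates
#'   below the maximum observed count are excluded; an error is raised if
#'   none remain.
#' @param objective `"sse"` (summed squared deviations of relative
#'   frequencies, default) or `"ml"` (multinomial likelihood).
#' @return A list of class `n_estimate`: `method = "binomial"`, `N_int`,
#'   `N_real` (equal to `N_int` here), `P_hat` (per stimulus, at the
#'   selected `N`), `fit_error`, `indeterminate` flag (all-zero counts),
#'   and `candidates` (per-candidate error table).
#' @examples
#' k <- rbinom(200, 4, 0.7)
#' fit_binomial_N(k)$N_int
#' @export
fit_binomial_N <- function(counts, n_range = 1:10,
                           objective = c("sse", "ml")) {
  objective <- match.arg(objective)
  if (!is.list(counts)) counts <- list(counts)
  counts <- lapply(counts, function(x) {
    if (any(x < 0) || any(x != round(x))) {
      stop("counts must be non-negative integers", call. = FALSE)
    }
    as.integer(x)
  })
  kmax <- max(vapply(counts, max, integer(1)))
  if (all(kmax == 0) && all(unlist(counts) == 0)) {
    return(structure(list(method = "binomial", N_int = NA_integer_,
                          N_real = NA_real_, P_hat = 0,
                          fit_error = NA_real_, indeterminate = TRUE,
                          candidates = NULL),
                     class = "n_estimate"))
  }
  cand <- sort(unique(as.integer(n_range)))
  cand <- cand[cand >= max(1L, kmax)]
  if (length(cand) == 0) {
    stop("no candidate N can hold the maximum observed count (",
         kmax, "); widen `n_range`", call. = FALSE)
  }

  fit_one <- function(N, k) {
    freq <- tabulate(k + 1L, nbins = N + 1L) / length(k)
    obj <- function(P) {
      pk <- stats::dbinom(0:N, N, P)
      if (objective == "sse") {
        sum((freq - pk)^2)
      } else {
        -sum(freq * length(k) * log(pmax(pk, 1e-300)))
      }
    }
    opt <- stats::optimize(obj, c(0, 1))
    list(P = opt$minimum, err = opt$objective)
  }

  tab <- lapply(cand, function(N) {
    fits <- lapply(counts, function(k) fit_one(N, k))
    list(N = N,
         err = sum(vapply(fits, `[[`, numeric(1), "err")),
         P = vapply(fits, `[[`, numeric(1), "P"))
  })
  errs <- vapply(tab, `[[`, numeric(1), "err")
  best <- which.min(errs)  # which.min takes the first, i.e. smallest N
  structure(list(method = "binomial",
                 N_int = tab[[best]]$N,
                 N_real = as.numeric(tab[[best]]$N),
                 P_hat = tab[[best]]$P,
                 fit_error = errs[best],
                 indeterminate = FALSE,
                 candidates = data.frame(N = cand, fit_error = errs)),
            class = "n_estimate")
}

#' Estimate the docking-site number by variance-mean analysis
#'
#' Fits the per-stimulus (mean, variance) points of a train with the
#' binomial parabola `var = m - m^2 / N`, i.e. a parabola through the
#' origin with initial slope 1 whose x-axis intercept is the maximal mean
#' count `N`.  The single free parameter `N` enters linearly through
#' `1/N`, so the least-squares solution is obtained in closed form by
#' regressing `m - var` on `m^2` without intercept; the standard error of
#' `N` follows by the delta method.
#'
#' @param stats A [summarize_counts()] result, or a data frame with
#'   columns `mean` and `var` (>= 3 points with distinct means).
#' @param weighted If `TRUE`, points are down-weighted by the approximate
#'   sampling variance of a variance estimate (proportional to `var^2`);
#'   the unweighted fit is the default because the underlying analysis
#'   does not state a weighting.
#' @return A list of class `n_estimate` with `method =
#'   "variance_mean"`, `N_real`, `N_int` (nearest integer), `stderr`,
#'   `fit_error` (residual sum of squares) and a `failed` flag.
#'   Degenerate inputs (all variances zero, or a non-positive fitted
#'   intercept) are flagged `failed = TRUE`; for all-zero variances
#'   `N_real` is reported as the largest mean.
#' @examples
#' m <- c(0.4, 1.2, 2.0, 2.8)
#' fit_variance_mean(data.frame(mean = m, var = m * (1 - m / 4)))$N_real
#' @export
fit_variance_mean <- function(stats, weighted = FALSE) {
  m <- stats$mean
  v <- stats$var
  if (length(m) < 3 || length(unique(round(m, 12))) < 3) {
    stop("variance-mean fitting needs >= 3 points with distinct means",
         call. = FALSE)
  }
  if (any(v < 0)) stop("variances must be non-negative", call. = FALSE)
  if (all(v == 0)) {
    return(structure(list(method = "variance_mean",
                          N_real = max(m), N_int = as.integer(round(max(m))),
                          stderr = NA_real_, fit_error = NA_real_,
                          failed = TRUE),
                     class = "n_estimate"))
  }
  w <- if (weighted) 1 / pmax(v, max(v) * 1e-3)^2 else rep(1, length(m))
  y <- m - v
  x <- m^2
  beta <- sum(w * x * y) / sum(w * x^2)
  rss <- sum(w * (y - beta * x)^2)
  dof <- length(m) - 1
  se_beta <- sqrt(rss / dof / sum(w * x^2))
  failed <- !is.finite(beta) || beta <= 0
  n_real <- if (failed) NA_real_ else 1 / beta
  structure(list(method = "variance_mean",
                 N_real = n_real,
                 N_int = if (failed) NA_integer_
                         else as.integer(round(n_real)),
                 stderr = if (failed) NA_real_ else se_beta / beta^2,
                 fit_error = rss,
                 failed = failed),
            class = "n_estimate")
}

#' @export
print.n_estimate <- function(x, ...) {
  cat(sprintf("<n_estimate> method = %s\n", x$method))
  if (isTRUE(x$indeterminate)) {
    cat("  indeterminate: all counts zero\n")
  } else if (isTRUE(x$failed)) {
    cat("  fit failed (degenerate variance-mean relation)\n")
    if (is.finite(x$N_real)) cat(sprintf("  N_real -> %.3g\n", x$N_real))
  } else {
    cat(sprintf("  N_int = %d, N_real = %.3g", x$N_int, x$N_real))
    if (!is.null(x$stderr) && is.finite(x$stderr)) {
      cat(sprintf(" (+/- %.2g)", x$stderr))
    }
    cat(sprintf(", fit error = %.4g\n", x$fit_error))
  }
  invisible(x)
}
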