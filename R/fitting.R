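#' Fit docking-model parameters to mean train responses
#'
#' Recovers the transition-probability parameters (`delta`, `p_r`, `r`,
#' `s`; `rho` is fixed at 1 by default) of a sequential docking model
#' from observed mean released-vesicle counts, by least squares over the
#' early part of the train (stimuli 1--5 by default, where the model is
#' most faithful; late-train counts are depressed by upstream-pool
#' depletion and inflated by asynchronous release, both outside the base
#' model).
#'
#' The search is a coarse grid over the free parameters followed by a
#' box-constrained local refinement.  Two loss backends are available:
#' the exact state-distribution recursion ([analytic_mean_si()];
#' deterministic, the default) and a Monte Carlo loss that simulates
#' `mc_reps` trains per evaluation using common random numbers (the same
#' seed for every evaluation), which keeps the stochastic objective
#' locally smooth.  The Monte Carlo backend starts from the analytic
#' optimum and applies a pattern search.
#'
#' Note the identifiability caveat: `delta` and `p_r` trade off through
#' the first-stimulus probability `P_1 = delta * p_r`, so with noisy
#' targets the individual estimates can drift along that ridge while
#' their product stays well determined.
#'
#' @param target A [summarize_counts()] result or numeric vector of mean
#'   counts per stimulus (per synapse; divided by `n_sites` internally).
#' @param model_kind `"RSDS"` or `"LSTS"`.
#' @param n_sites Docking sites of the observed synapse; taken from the
#'   `stimulus_stats` attribute when present.
#' @param fit_range Stimulus indices entering the loss (default `1:5`).
#' @param fixed Named numeric vector of parameters held fixed (default
#'   `c(rho = 1)`).
#' @param loss `"analytic"` or `"mc"`.
#' @param mc_reps Trains per Monte Carlo loss evaluation (default 5000).
#' @param protocol Protocol for the Monte Carlo backend; the analytic
#'   recursion only needs the number of stimuli.
#' @param grid_step Coarse grid spacing over free parameters (default
#'   0.05).
#' @param seed Seed for the common-random-number stream (Monte Carlo
#'   backend); repeated fits with the same seed are identical.
#' @return A list of class `fit_result`: `params_hat`
#'   ([model_params()]), `loss_value`, `n_evaluations`, `converged`,
#'   `loss`, `seed`.
#' @examples
#' truth <- condition_params("control", n_sites = 1)
#' fit <- fit_model(analytic_mean_si(truth, 8), "RSDS", n_sites = 1)
#' fit$params_hat
#' @export
fit_model <- function(target, model_kind = c("RSDS", "LSTS"),
                      n_sites = NULL, fit_range = 1:5,
                      fixed = c(rho = 1), loss = c("analytic", "mc"),
                      mc_reps = 5000, protocol = NULL,
                      grid_step = 0.05, seed = 1L) {
  model_kind <- match.arg(model_kind)
  loss <- match.arg(loss)
  if (inherits(target, "stimulus_stats")) {
    if (is.null(n_sites)) n_sites <- attr(target, "n_sites")
    target <- target$mean
  }
  if (is.null(n_sites)) {
    stop("`n_sites` is required (or supply stats carrying it)",
         call. = FALSE)
  }
  target <- as.numeric(target) / n_sites
  n_stim <- length(target)
  fit_range <- as.integer(fit_range)
  if (any(fit_range < 1 | fit_range > n_stim)) {
    stop("`fit_range` must lie within the train", call. = FALSE)
  }
  if (mc_reps < 100) stop("`mc_reps` must be >= 100", call. = FALSE)

  all_par <- c("delta", "rho", "p_r", "r", "s")
  if (!all(names(fixed) %in% all_par)) {
    stop("unknown parameter name in `fixed`", call. = FALSE)
  }
  free <- setdiff(all_par, names(fixed))
  n_eval <- 0L

  full_par <- function(theta) {
    p <- c(as.list(fixed), as.list(stats::setNames(theta, free)))
    p[all_par]
  }
  analytic_loss_grid <- function(grid) {
    ## grid: matrix [k x length(free)]
    p <- lapply(all_par, function(nm) {
      if (nm %in% names(fixed)) fixed[[nm]] else grid[, nm]
    })
    names(p) <- all_par
    pred <- analytic_mean_si_vec(model_kind, p$delta, p$rho, p$p_r,
                                 p$r, p$s, n_stim)
    rowSums((pred[, fit_range, drop = FALSE] -
               rep(target[fit_range], each = nrow(grid)))^2)
  }
  analytic_loss1 <- function(theta) {
    g <- matrix(theta, 1, dimnames = list(NULL, free))
    n_eval <<- n_eval + 1L
    analytic_loss_grid(g)
  }
  mc_loss1 <- function(theta) {
    p <- full_par(theta)
    mp <- model_params(model_kind, n_sites = 1, delta = p$delta,
                       rho = p$rho, p_r = p$p_r, r = p$r, s = p$s)
    prot <- if (is.null(protocol)) train_protocol(n_stim, 100, mc_reps)
            else train_protocol(n_stim, protocol$freq_hz, mc_reps)
    cm <- simulate_trains(mp, prot, seed = seed)  # common random numbers
    n_eval <<- n_eval + 1L
    sum((colMeans(cm$counts)[fit_range] - target[fit_range])^2)
  }

  ## coarse grid (analytic loss -- exact and cheap, vectorised)
  vals <- seq(0, 1, by = grid_step)
  grid <- as.matrix(expand.grid(stats::setNames(
    rep(list(vals), length(free)), free)))
  gl <- analytic_loss_grid(grid)
  n_eval <- n_eval + nrow(grid)
  theta <- grid[which.min(gl), ]

  ## local refinement
  converged <- TRUE
  opt <- stats::optim(theta, analytic_loss1, method = "L-BFGS-B",
                      lower = 0, upper = 1)
  if (opt$value <= min(gl)) {
    theta <- opt$par
  } else if (opt$convergence != 0) {
    warning("local refinement did not converge; returning best grid point")
    converged <- FALSE
  }

  if (loss == "mc") {
    theta <- pattern_search(theta, mc_loss1, lower = 0, upper = 1,
                            step = grid_step)
  }
  p <- full_par(theta)
  best_loss <- if (loss == "mc") mc_loss1(theta) else analytic_loss1(theta)
  structure(list(params_hat = model_params(
                   model_kind, n_sites = n_sites, delta = p$delta,
                   rho = p$rho, p_r = p$p_r, r = p$r, s = p$s),
                 loss_value = unname(best_loss),
                 n_evaluations = n_eval,
                 converged = converged,
                 loss = loss, seed = seed, fit_range = fit_range),
            class = "fit_result")
}

#' Fit the intermediate-pool extension on top of a base model
#'
#' With the base transition parameters frozen (as obtained from
#' [fit_model()]), fits the two intermediate-pool parameters -- the
#' initial pool size `ip_size0` (integer grid) and the per-vacancy refill
#' probability `r_ip` -- to the mean train response.  The loss covers the
#' whole train by default, since the pool mainly shapes the late-train
#' response.  The loss is Monte Carlo with common random numbers (the
#' pool couples the sites, so no product-form recursion exists); the
#' `r_ip` axis is refined by pattern search after the grid stage.
#'
#' @param target As in [fit_model()].
#' @param base_params A [model_params()] with the frozen base parameters.
#' @param fit_range Stimulus indices for the loss (default: full train).
#' @param ip_size_range Candidate initial pool sizes (default `0:30`,
#'   per synapse).
#' @param r_ip_grid Candidate refill probabilities (default step 0.1).
#' @param couple_s_to_ip Scale `s` by the pool filling fraction
#'   (default TRUE).
#' @param mc_reps,protocol,seed As in [fit_model()].
#' @return A `fit_result` with an `ip_hat` ([ip_params()]) element.
#' @export
fit_ip_extension <- function(target, base_params, fit_range = NULL,
                             ip_size_range = 0:30,
                             r_ip_grid = seq(0, 1, by = 0.1),
                             couple_s_to_ip = TRUE,
                             mc_reps = 5000, protocol = NULL, seed = 1L) {
  stopifnot(inherits(base_params, "model_params"))
  if (inherits(target, "stimulus_stats")) target <- target$mean
  target <- as.numeric(target) / base_params$n_sites
  n_stim <- length(target)
  if (is.null(fit_range)) fit_range <- seq_len(n_stim)
  prot <- train_protocol(n_stim,
                         if (is.null(protocol)) 100 else protocol$freq_hz,
                         mc_reps)
  n_eval <- 0L

  ip_loss <- function(size, r_ip) {
    ip <- ip_params(round(size), min(max(r_ip, 0), 1), couple_s_to_ip)
    cm <- simulate_trains(base_params, prot, ip = ip, seed = seed)
    n_eval <<- n_eval + 1L
    sum((colMeans(cm$counts)[fit_range] / base_params$n_sites -
           target[fit_range])^2)
  }

  grid <- expand.grid(size = ip_size_range, r_ip = r_ip_grid)
  gl <- mapply(ip_loss, grid$size, grid$r_ip)
  best <- grid[which.min(gl), ]
  ## refine r_ip (and neighbouring integer sizes) by pattern search
  r_hat <- pattern_search(best$r_ip,
                          function(x) ip_loss(best$size, x),
                          lower = 0, upper = 1, step = 0.05)
  sizes <- intersect(best$size + (-1:1), ip_size_range)
  ls <- vapply(sizes, function(sz) ip_loss(sz, r_hat), numeric(1))
  size_hat <- sizes[which.min(ls)]

  structure(list(params_hat = base_params,
                 ip_hat = ip_params(size_hat, r_hat, couple_s_to_ip),
                 loss_value = min(ls),
                 n_evaluations = n_eval,
                 converged = TRUE,
                 loss = "mc", seed = seed, fit_range = fit_range),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> loss = %s, value = %.4g (%d evaluations)%s\n",
              x$loss, x$loss_value, x$n_evaluations,
              if (x$converged) "" else " [not converged]"))
  print(x$params_hat)
  if (!is.null(x$ip_hat)) {
    cat(sprintf("  IP: size0 = %d, r_ip = %.3g\n",
                x$ip_hat$ip_size0, x$ip_hat$r_ip))
  }
  invisible(x)
}

## Coordinate pattern search with step halving on a box; tolerant of a
## stochastic objective when common random numbers make it a fixed
## function of the parameters.
pattern_search <- function(theta, fn, lower = 0, upper = 1,
                           step = 0.05, tol = 1e-3, max_iter = 200) {
  theta <- pmin(pmax(theta, lower), upper)
  f0 <- fn(theta)
  it <- 0
  while (step > tol && it < max_iter) {
    improved <- FALSE
    for (j in seq_along(theta)) {
      for (dir in c(1, -1)) {
        cand <- theta
        cand[j] <- min(max(cand[j] + dir * step, lower), upper)
        if (cand[j] == theta[j]) next
        fc <- fn(cand)
        it <- it + 1
        if (fc < f0) {
          theta <- cand
          f0 <- fc
          improved <- TRUE
        }
      }
    }
    if (!improved) step <- step / 2
  }
  theta
}
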