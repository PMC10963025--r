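#' Monte Carlo simulation of sequential docking and release during trains
#'
#' Simulates per-train, per-stimulus released-vesicle counts for a synapse
#' with `n_sites` independent release units obeying either the two-slot
#' RS/DS model or the one-slot LS/TS model, optionally limited by a shared
#' upstream intermediate pool.
#'
#' @section Update cycle:
#' Each action potential triggers one cycle.  Under the default
#' (`scheduling = "blocked"`) the order within a cycle is:
#' \enumerate{
#'   \item release: every occupied DS (tight slot) vesicle fuses with
#'     probability `p_r` and is counted;
#'   \item docking: every unit with an empty DS and an occupied RS moves
#'     the RS vesicle to the DS with probability `r` (loose to tight for
#'     LS/TS); a vesicle arriving at the DS cannot fuse until the next
#'     action potential;
#'   \item replenishment: every empty RS (empty slot for LS/TS) fills with
#'     probability `s` from upstream, decrementing the intermediate pool
#'     when one is present; a vesicle arriving here cannot take the
#'     docking step until the next interval;
#'   \item pool refill: every intermediate-pool vacancy fills with
#'     probability `r_ip` from the recycling pool.
#' }
#' With `scheduling = "chained"` a vesicle replenished in step 3 is given
#' an immediate extra docking attempt (probability `r`) if the DS is still
#' empty, i.e. replenished vesicles may chain two transitions in one
#' interval.  With `scheduling = "split_interval"` the inter-stimulus
#' interval is split into two half-intervals, each applying docking then
#' replenishment with half-interval probabilities `1 - sqrt(1 - r)` and
#' `1 - sqrt(1 - s)`, so a vesicle replenished early in the interval can
#' advance late in the same interval.  The variants matter only for how
#' replenished vesicles propagate within one interval; all reduce to the
#' same first-stimulus law.
#'
#' When an intermediate pool is supplied and `couple_s_to_ip` is set, the
#' per-site replenishment probability is scaled by the instantaneous pool
#' filling fraction; replenishment always stops when the pool is empty.
#'
#' Initial occupancies are drawn independently per site and per train
#' (trains are far apart in time and treated as independent).  Random
#' draws are consumed in a fixed, documented order (per cycle: release
#' block, docking block, then replenishment site-by-site, then pool
#' refill), so a given `seed` reproduces results exactly.
#'
#' @param params A [model_params()] object.
#' @param protocol A [train_protocol()] object.
#' @param ip Optional [ip_params()] object (intermediate-pool extension).
#' @param seed Optional integer seed; the global RNG state is restored on
#'   exit.
#' @param scheduling Intra-interval scheduling variant, see above.
#'
#' @return A `count_matrix` object: a list with elements `counts` (an
#'   `n_trains` by `n_stim` integer matrix with columns `stim_1 ...`),
#'   `protocol`, `normalization` (`"per_synapse"`), and the generating
#'   `params`, `ip`, `seed` and `scheduling`.
#' @examples
#' p <- condition_params("control")
#' cm <- simulate_trains(p, train_protocol(8, 100, 200), seed = 1)
#' colMeans(cm$counts)
#' @export
simulate_trains <- function(params, protocol, ip = NULL, seed = NULL,
                            scheduling = c("blocked", "chained",
                                           "split_interval")) {
  stopifnot(inherits(params, "model_params"),
            inherits(protocol, "train_protocol"))
  if (!is.null(ip)) stopifnot(inherits(ip, "ip_params"))
  scheduling <- match.arg(scheduling)
  local_seed(seed)

  counts <- if (params$model_kind == "RSDS") {
    sim_rsds(params, protocol, ip, scheduling)
  } else {
    sim_lsts(params, protocol, ip, scheduling)
  }
  colnames(counts) <- paste0("stim_", seq_len(protocol$n_stim))
  new_count_matrix(counts, protocol, params = params, ip = ip,
                   seed = seed, scheduling = scheduling)
}

## Two-slot model: logical matrices rs, ds over (train, site).
sim_rsds <- function(params, protocol, ip, scheduling) {
  nt <- protocol$n_trains
  N  <- params$n_sites
  n  <- nt * N
  rs <- matrix(stats::runif(n) < params$rho,   nt, N)
  ds <- matrix(stats::runif(n) < params$delta, nt, N)
  st <- init_ip_state(ip, nt)
  counts <- matrix(0L, nt, protocol$n_stim)

  for (i in seq_len(protocol$n_stim)) {
    ## (1) release
    fuse <- ds & matrix(stats::runif(n) < params$p_r, nt, N)
    counts[, i] <- as.integer(rowSums(fuse))
    ds <- ds & !fuse
    if (scheduling == "split_interval") {
      r_h <- 1 - sqrt(1 - params$r)
      s_h <- 1 - sqrt(1 - params$s)
      for (half in 1:2) {
        mv <- rs & !ds & matrix(stats::runif(n) < r_h, nt, N)
        ds <- ds | mv
        rs <- rs & !mv
        rp <- replenish_sites(!rs, s_h, st, nt, N)
        rs <- rs | rp$filled
        st <- rp$state
      }
    } else {
      ## (2) docking
      mv <- rs & !ds & matrix(stats::runif(n) < params$r, nt, N)
      ds <- ds | mv
      rs <- rs & !mv
      ## (3) replenishment
      rp <- replenish_sites(!rs, params$s, st, nt, N)
      rs <- rs | rp$filled
      st <- rp$state
      if (scheduling == "chained") {
        ## replenished vesicles get one immediate docking attempt
        mv2 <- rp$filled & !ds & matrix(stats::runif(n) < params$r, nt, N)
        ds <- ds | mv2
        rs <- rs & !mv2
      }
    }
    ## (4) intermediate-pool refill
    st <- refill_ip(st)
  }
  counts
}

## One-slot model: integer state matrix, 0 = empty, 1 = loose, 2 = tight.
sim_lsts <- function(params, protocol, ip, scheduling) {
  nt <- protocol$n_trains
  N  <- params$n_sites
  n  <- nt * N
  state <- matrix(0L, nt, N)
  tight0 <- matrix(stats::runif(n) < params$delta, nt, N)
  loose0 <- !tight0 & matrix(stats::runif(n) < params$rho, nt, N)
  state[tight0] <- 2L
  state[loose0] <- 1L
  st <- init_ip_state(ip, nt)
  counts <- matrix(0L, nt, protocol$n_stim)

  step_dock <- function(state, p) {
    mv <- state == 1L & matrix(stats::runif(n) < p, nt, N)
    state[mv] <- 2L
    state
  }
  step_replenish <- function(state, p, st) {
    rp <- replenish_sites(state == 0L, p, st, nt, N)
    state[rp$filled] <- 1L
    list(state = state, st = rp$state, filled = rp$filled)
  }

  for (i in seq_len(protocol$n_stim)) {
    fuse <- state == 2L & matrix(stats::runif(n) < params$p_r, nt, N)
    counts[, i] <- as.integer(rowSums(fuse))
    state[fuse] <- 0L
    if (scheduling == "split_interval") {
      r_h <- 1 - sqrt(1 - params$r)
      s_h <- 1 - sqrt(1 - params$s)
      for (half in 1:2) {
        state <- step_dock(state, r_h)
        rp <- step_replenish(state, s_h, st)
        state <- rp$state
        st <- rp$st
      }
    } else {
      state <- step_dock(state, params$r)
      rp <- step_replenish(state, params$s, st)
      state <- rp$state
      st <- rp$st
      if (scheduling == "chained") {
        mv <- rp$filled & matrix(stats::runif(n) < params$r, nt, N)
        state[mv] <- 2L
      }
    }
    st <- refill_ip(st)
  }
  counts
}

## ---- intermediate-pool bookkeeping ------------------------------------

init_ip_state <- function(ip, n_trains) {
  if (is.null(ip)) return(NULL)
  list(ip = rep.int(ip$ip_size0, n_trains), params = ip)
}

## Fill eligible (empty) positions with per-site probability `s`, limited
## by the per-train pool stock and scaled by the filling fraction when
## coupled.  Sites are processed in column order so the draw sequence is
## deterministic for a given seed.
replenish_sites <- function(eligible, s, st, nt, N) {
  if (is.null(st)) {
    filled <- eligible & matrix(stats::runif(nt * N) < s, nt, N)
    return(list(filled = filled, state = NULL))
  }
  ipar <- st$params
  pool <- st$ip
  filled <- matrix(FALSE, nt, N)
  for (j in seq_len(N)) {
    s_eff <- if (ipar$couple_s_to_ip && ipar$ip_size0 > 0) {
      s * pool / ipar$ip_size0
    } else {
      rep.int(s, nt)
    }
    ok <- eligible[, j] & pool > 0L & stats::runif(nt) < s_eff
    filled[, j] <- ok
    pool <- pool - as.integer(ok)
  }
  list(filled = filled, state = list(ip = pool, params = ipar))
}

refill_ip <- function(st) {
  if (is.null(st)) return(NULL)
  ipar <- st$params
  vac <- ipar$ip_size0 - st$ip
  st$ip <- st$ip + stats::rbinom(length(vac), vac, ipar$r_ip)
  st
}

## ---- closed-form helpers ----------------------------------------------

#' Release probability at the first stimulus
#'
#' The probability that a docking site releases a vesicle at the first
#' action potential of a train is the product of the initial docking-site
#' occupancy and the docked-vesicle release probability,
#' `P_1 = delta * p_r`.  It is identical for both model variants.
#'
#' @param params A [model_params()] object.
#' @return A probability.
#' @examples
#' analytic_P1(condition_params("control"))  # 0.39
#' @export
analytic_P1 <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$delta * params$p_r
}

#' Release probability at the second stimulus (two-slot model)
#'
#' Exact one-step recursion for the second-stimulus release probability of
#' the RS/DS model under the blocked update order:
#' `P_2 = p_r * (delta * (1 - p_r) + (1 - delta * (1 - p_r)) * rho * r)`.
#' The first term is a surviving docked vesicle; the second is a
#' replacement vesicle that moved down during the first interval.  The
#' commonly used approximation `rho * r * p_r` (exact when `delta * (1 -
#' p_r)` is negligible) is returned alongside.
#'
#' @param params A [model_params()] object with `model_kind == "RSDS"`.
#' @return A list with `exact` and `approx` probabilities.
#' @examples
#' analytic_P2_rsds(condition_params("control"))$exact  # 0.467
#' @export
analytic_P2_rsds <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$model_kind != "RSDS") {
    stop("`analytic_P2_rsds()` is defined for the RSDS model only",
         call. = FALSE)
  }
  survive <- params$delta * (1 - params$p_r)
  exact <- params$p_r * (survive + (1 - survive) * params$rho * params$r)
  list(exact = exact, approx = params$rho * params$r * params$p_r)
}

#' Maximum readily-releasable-pool size per docking site
#'
#' Runs the simulator in the fully primed, deterministic limit (all
#' occupancies and transition probabilities 1, no replenishment) and
#' returns the total number of vesicles released per docking site over a
#' train.  The two-slot RS/DS model yields 2 (both slots hold a vesicle);
#' the one-slot LS/TS model yields 1.
#'
#' @param model_kind `"RSDS"` or `"LSTS"`.
#' @param n_stim Train length used for the check (>= 2).
#' @return An integer, 2 or 1.
#' @examples
#' max_rrp_per_site("RSDS")  # 2
#' max_rrp_per_site("LSTS")  # 1
#' @export
max_rrp_per_site <- function(model_kind = c("RSDS", "LSTS"), n_stim = 8) {
  model_kind <- match.arg(model_kind)
  p <- model_params(model_kind, n_sites = 1, delta = 1, rho = 1,
                    p_r = 1, r = 1, s = 0)
  cm <- simulate_trains(p, train_protocol(n_stim, 100, 1), seed = 1L)
  as.integer(sum(cm$counts))
}

#' Exact mean release counts per stimulus (no intermediate pool)
#'
#' Propagates the single-site state distribution exactly through a train
#' and returns the expected released-vesicle count per site at each
#' stimulus.  For the RS/DS model the state is the joint (RS, DS)
#' occupancy (four states); for LS/TS it is the slot state (three
#' states).  Only the `"blocked"` update order is implemented; sites are
#' independent, so per-synapse means are `n_sites` times the returned
#' values.  Used as the fast deterministic loss in model fitting.
#'
#' @param params A [model_params()] object.
#' @param n_stim Number of stimuli.
#' @return Numeric vector of length `n_stim`: expected counts per site.
#' @seealso [fit_model()]
#' @export
analytic_mean_si <- function(params, n_stim = 8) {
  stopifnot(inherits(params, "model_params"))
  m <- analytic_mean_si_vec(
    params$model_kind, params$delta, params$rho,
    params$p_r, params$r, params$s, n_stim)
  as.numeric(m)
}

## Vectorised over parameter vectors (equal length); returns a matrix
## [n_par x n_stim].  Elementwise state-probability propagation so a whole
## parameter grid is evaluated in one pass.
analytic_mean_si_vec <- function(model_kind, delta, rho, p_r, r, s,
                                 n_stim) {
  k <- max(length(delta), length(rho), length(p_r), length(r), length(s))
  delta <- rep_len(delta, k); rho <- rep_len(rho, k)
  p_r <- rep_len(p_r, k); r <- rep_len(r, k); s <- rep_len(s, k)
  out <- matrix(0, k, n_stim)
  if (model_kind == "RSDS") {
    ## joint P(rs = a, ds = b)
    p11 <- rho * delta; p10 <- rho * (1 - delta)
    p01 <- (1 - rho) * delta; p00 <- (1 - rho) * (1 - delta)
    for (i in seq_len(n_stim)) {
      ds_occ <- p11 + p01
      out[, i] <- ds_occ * p_r
      ## release: occupied ds fuses with prob p_r
      a11 <- p11 * (1 - p_r); a10 <- p10 + p11 * p_r
      a01 <- p01 * (1 - p_r); a00 <- p00 + p01 * p_r
      ## docking: (rs = 1, ds = 0) -> (0, 1) with prob r
      b11 <- a11
      b10 <- a10 * (1 - r)
      b01 <- a01 + a10 * r
      b00 <- a00
      ## replenishment (rs empty)
      p11 <- b11 + b01 * s
      p10 <- b10 + b00 * s
      p01 <- b01 * (1 - s)
      p00 <- b00 * (1 - s)
    }
  } else {
    pT <- delta; pL <- (1 - delta) * rho; pE <- 1 - pT - pL
    for (i in seq_len(n_stim)) {
      out[, i] <- pT * p_r
      aT <- pT * (1 - p_r); aE <- pE + pT * p_r; aL <- pL
      bT <- aT + aL * r; bL <- aL * (1 - r); bE <- aE
      pT <- bT
      pL <- bL + bE * s
      pE <- bE * (1 - s)
    }
  }
  out
}

#' Replacement-site occupancy before the second stimulus
#'
#' Closed-form diagnostic for the state of the distal (replacement) site
#' at the end of the first inter-stimulus interval in the RS/DS model:
#' total occupancy and the share contributed by vesicles replenished from
#' upstream during that interval, under each scheduling variant.  Under
#' `"blocked"` scheduling replenished vesicles reach the RS but cannot
#' advance further within the interval; under `"chained"` they may dock
#' immediately when the DS is free.  These accounting choices change the
#' replenishment-origin share substantially, which is why the scheduling
#' is exposed as an option.
#'
#' @param params A [model_params()] with `model_kind == "RSDS"`.
#' @param scheduling `"blocked"` or `"chained"`.
#' @return A list with `rho2_total` (RS occupancy before stimulus 2) and
#'   `rho2_replenishment` (part of it that arrived during the interval).
#' @export
rs_occupancy_before_stim2 <- function(params,
                                      scheduling = c("blocked", "chained")) {
  stopifnot(inherits(params, "model_params"), params$model_kind == "RSDS")
  scheduling <- match.arg(scheduling)
  ds_empty <- 1 - params$delta * (1 - params$p_r)  # after release at AP 1
  moved <- params$rho * ds_empty * params$r        # RS emptied by docking
  native <- params$rho - moved
  refill <- (1 - params$rho + moved) * params$s
  if (scheduling == "chained") {
    ## a refilled RS vesicle docks at once when the DS is still empty;
    ## with the DS filled by the moved vesicle this only matters when the
    ## docking step failed for lack of an RS vesicle
    chain <- (1 - params$rho) * params$s * ds_empty * params$r
    refill <- refill - chain
  }
  list(rho2_total = native + refill, rho2_replenishment = refill)
}

## ---- seed handling -----------------------------------------------------

## set.seed() scoped to the calling simulate/generate call: the global
## RNG state is restored when the caller exits.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  }
  ## register `restore()` to run when the *caller* exits
  do.call(on.exit, list(as.call(list(restore)), TRUE), envir = env)
  set.seed(seed)
  invisible(NULL)
}
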