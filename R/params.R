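#' Model parameters for sequential docking-site models
#'
#' Bundles the transition probabilities of a discrete-time sequential
#' docking model together with the model variant and the number of docking
#' sites per synapse.
#'
#' Two variants are supported.  In the two-slot `"RSDS"` model each release
#' unit has a distal replacement site (RS) and a proximal docking site (DS)
#' that can be occupied simultaneously, so a full unit holds two vesicles.
#' In the one-slot `"LSTS"` model a single slot holds at most one vesicle,
#' in either a loose (immature) or tight (release-ready) state.
#'
#' All transition probabilities are defined per inter-stimulus interval and
#' are not rescaled when the stimulation frequency changes; identical
#' parameter values therefore mean different underlying rates at 100 and
#' 200 Hz.  Use [rate_to_interval_prob()] if a rate-based parameterisation
#' is wanted.
#'
#' @param model_kind `"RSDS"` (two-slot replacement-site/docking-site) or
#'   `"LSTS"` (one-slot loose/tight state).
#' @param n_sites Number of docking sites per synapse (positive integer).
#' @param delta Initial occupancy probability of the proximal site
#'   (DS occupied for RSDS; slot in the tight state for LSTS).
#' @param rho Initial occupancy probability of the distal position: the RS
#'   for RSDS, or -- for LSTS -- the probability that a slot not in the
#'   tight state holds a loose vesicle.
#' @param p_r Release probability of a release-ready (DS/tight) vesicle per
#'   action potential.
#' @param r Per-interval probability of the distal-to-proximal transition
#'   (RS to DS, or loose to tight) when the proximal position is free.
#' @param s Per-interval probability that an empty distal position (empty
#'   RS, or empty slot for LSTS) is refilled from upstream pools.
#'
#' @return An object of class `model_params` (a named list).
#' @seealso [simulate_trains()], [analytic_P1()], [analytic_P2_rsds()]
#' @examples
#' ## fitted control-condition parameters for the two-slot model
#' model_params("RSDS", n_sites = 4, delta = 0.65, rho = 1,
#'              p_r = 0.6, r = 0.7, s = 0.35)
#' @export
model_params <- function(model_kind = c("RSDS", "LSTS"), n_sites = 1,
                         delta = 0.5, rho = 1, p_r = 0.5, r = 0.5, s = 0.2) {
  model_kind <- match.arg(model_kind)
  n_sites <- check_count(n_sites, "n_sites", min = 1)
  for (nm in c("delta", "rho", "p_r", "r", "s")) {
    check_prob(get(nm), nm)
  }
  structure(list(model_kind = model_kind, n_sites = n_sites,
                 delta = delta, rho = rho, p_r = p_r, r = r, s = s),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> %s, N = %d sites\n  delta = %.3g, rho = %.3g, p_r = %.3g, r = %.3g, s = %.3g\n",
    x$model_kind, x$n_sites, x$delta, x$rho, x$p_r, x$r, x$s))
  invisible(x)
}

#' Intermediate-pool parameters
#'
#' Parameters of the small upstream vesicle pool (the intermediate pool,
#' IP) that feeds the replacement sites of a synapse.  The pool is shared
#' between all docking sites of the synapse and is itself refilled from an
#' effectively infinite recycling pool.
#'
#' @param ip_size0 Initial number of vesicles in the pool (the reported
#'   fitted range is 10--15 vesicles for a synapse with four docking
#'   sites).
#' @param r_ip Per-interval, per-vacancy refill probability of the pool
#'   from the recycling pool.
#' @param couple_s_to_ip If `TRUE` (default), the replenishment
#'   probability `s` is scaled by the instantaneous filling fraction of
#'   the pool (`ip_now / ip_size0`), so replenishment slows as the pool
#'   empties.
#'
#' @return An object of class `ip_params`.
#' @export
ip_params <- function(ip_size0 = 12, r_ip = 0.2, couple_s_to_ip = TRUE) {
  ip_size0 <- check_count(ip_size0, "ip_size0", min = 0)
  check_prob(r_ip, "r_ip")
  stopifnot(is.logical(couple_s_to_ip), length(couple_s_to_ip) == 1)
  structure(list(ip_size0 = ip_size0, r_ip = r_ip,
                 couple_s_to_ip = couple_s_to_ip),
            class = "ip_params")
}

#' Stimulation-train protocol
#'
#' @param n_stim Number of action potentials per train (typically 8).
#' @param freq_hz Stimulation frequency in Hz (100 or 200 in the emulated
#'   recordings); the inter-stimulus interval is `1000 / freq_hz` ms.
#' @param n_trains Number of independent train repetitions.
#'
#' @return An object of class `train_protocol`.
#' @export
train_protocol <- function(n_stim = 8, freq_hz = 100, n_trains = 1) {
  n_stim <- check_count(n_stim, "n_stim", min = 1)
  n_trains <- check_count(n_trains, "n_trains", min = 1)
  if (!is.numeric(freq_hz) || length(freq_hz) != 1 || !is.finite(freq_hz) ||
      freq_hz <= 0) {
    stop("`freq_hz` must be a positive number", call. = FALSE)
  }
  structure(list(n_stim = n_stim, freq_hz = freq_hz, n_trains = n_trains),
            class = "train_protocol")
}

#' Inter-stimulus interval of a protocol, in ms
#' @param protocol A [train_protocol()].
#' @return Interval between successive stimuli in milliseconds.
#' @export
interval_ms <- function(protocol) 1000 / protocol$freq_hz

#' Convert a rate constant to a per-interval transition probability
#'
#' Optional rate-based parameterisation: `p = 1 - exp(-lambda * dt)` maps a
#' first-order rate `lambda` (per ms) to the probability that the
#' transition occurs at least once within an interval of `dt` ms.
#'
#' @param lambda Rate constant, per ms (non-negative).
#' @param dt_ms Interval duration in ms.
#' @return Transition probability in `[0, 1]`.
#' @export
rate_to_interval_prob <- function(lambda, dt_ms) {
  if (any(lambda < 0) || any(dt_ms < 0)) {
    stop("`lambda` and `dt_ms` must be non-negative", call. = FALSE)
  }
  1 - exp(-lambda * dt_ms)
}

#' Release-latency model
#'
#' Latency distributions attached to simulated release events.  Observed
#' single-synapse latency histograms are biphasic: a fast exponential
#' component (docked-vesicle release, time constant `tau_fast_ms`) and a
#' slow component (two-step release originating from the replacement site,
#' `tau_slow_ms`).  The slow share grows along the train; the default ramp
#' goes from 0 at stimulus 1 to 0.5 at stimulus 8, matching the reported
#' trend.  `onset_delay_ms` shifts the whole rising phase to the right
#' (0.2 ms under potassium-channel block, 0 otherwise).
#'
#' @param tau_fast_ms Fast time constant, ms (default 0.47).
#' @param tau_slow_ms Slow time constant, ms (default 4.0).
#' @param slow_fraction_by_stimulus Either a function of the stimulus
#'   index returning the slow-component weight, or a numeric vector
#'   indexed by stimulus.  Default: linear ramp 0 at i = 1 to 0.5 at
#'   i = 8, constant thereafter.
#' @param onset_delay_ms Fixed delay added to every latency, ms.
#'
#' @return An object of class `latency_model`.
#' @export
latency_model <- function(tau_fast_ms = 0.47, tau_slow_ms = 4.0,
                          slow_fraction_by_stimulus = NULL,
                          onset_delay_ms = 0) {
  stopifnot(tau_fast_ms > 0, tau_slow_ms > 0, onset_delay_ms >= 0)
  if (tau_fast_ms >= tau_slow_ms) {
    stop("`tau_fast_ms` must be smaller than `tau_slow_ms`", call. = FALSE)
  }
  if (is.null(slow_fraction_by_stimulus)) {
    slow_fraction_by_stimulus <- function(i) pmin((i - 1) / 7, 1) * 0.5
  } else if (is.numeric(slow_fraction_by_stimulus)) {
    v <- slow_fraction_by_stimulus
    if (any(v < 0 | v > 1)) stop("slow fractions must lie in [0, 1]",
                                 call. = FALSE)
    slow_fraction_by_stimulus <- function(i) v[pmin(i, length(v))]
  }
  stopifnot(is.function(slow_fraction_by_stimulus))
  structure(list(tau_fast_ms = tau_fast_ms, tau_slow_ms = tau_slow_ms,
                 slow_fraction_by_stimulus = slow_fraction_by_stimulus,
                 onset_delay_ms = onset_delay_ms),
            class = "latency_model")
}

#' Reference fitted parameter sets for the emulated experimental conditions
#'
#' Returns the fitted two-slot model parameters for the three emulated
#' experimental conditions at this synapse type: control (3 mM external
#' calcium), after addition of the potassium-channel blocker
#' 4-aminopyridine (`"4AP"`, which raises the release probability), and
#' during post-tetanic potentiation in 4-AP (`"PTP"`, which raises the
#' docking-site occupancy).  The distal-site occupancy `rho` is 1
#' throughout.
#'
#' @param condition `"control"`, `"4AP"` or `"PTP"`.
#' @param n_sites Docking sites per synapse (default 4).
#' @return A [model_params()] object.
#' @examples
#' condition_params("control")
#' @export
condition_params <- function(condition = c("control", "4AP", "PTP"),
                             n_sites = 4) {
  condition <- match.arg(condition)
  p <- switch(condition,
    control = list(delta = 0.65, p_r = 0.6),
    `4AP`   = list(delta = 0.8,  p_r = 0.9),
    PTP     = list(delta = 0.9,  p_r = 0.9))
  model_params("RSDS", n_sites = n_sites, delta = p$delta, rho = 1,
               p_r = p$p_r, r = 0.7, s = 0.35)
}

## ---- internal validators ----------------------------------------------

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x != round(x) || x < min) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
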