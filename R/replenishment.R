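#' Share of two-step release captured in the synchronous window
#'
#' Two-step release (replacement-site vesicles docking and fusing within
#' one inter-stimulus interval) follows an approximately exponential time
#' course.  Its share of the synchronous count is the asymptotic
#' amplitude attenuated by the fraction of that exponential falling
#' inside the measurement window:
#' `ratio = amp * (1 - exp(-window / tau))`.
#'
#' @param amp Asymptotic two-step share of synchronous release, in
#'   `[0, 1]` (0.2 after the second stimulus under strong potentiation).
#' @param window_ms Synchronous measurement window, ms (default 5).
#' @param tau_ms Time constant of the two-step release component, ms
#'   (default 4).
#' @return The attenuated share, in `[0, 1]`.
#' @examples
#' two_step_ratio(0.2, 5, 4)  # ~0.14
#' @export
two_step_ratio <- function(amp, window_ms = 5, tau_ms = 4) {
  check_prob(amp, "amp")
  if (!is.numeric(tau_ms) || tau_ms <= 0) {
    stop("`tau_ms` must be positive", call. = FALSE)
  }
  if (!is.numeric(window_ms) || window_ms < 0) {
    stop("`window_ms` must be non-negative", call. = FALSE)
  }
  amp * (1 - exp(-window_ms / tau_ms))
}

#' Replenishment-contribution breakdown
#'
#' Bundles the quantities needed to assess how much of the
#' second-stimulus release probability is due to vesicles replenished
#' from upstream pools during the first inter-stimulus interval:
#' the replacement-site occupancy at the end of that interval
#' (`rho2_total`), the part of it contributed by replenishment
#' (`rho2_replenishment`), and the parameters of the two-step share (see
#' [two_step_ratio()]).
#'
#' @param rho2_total Replacement-site occupancy before stimulus 2.
#' @param rho2_replenishment Replenishment-origin part of it (must not
#'   exceed `rho2_total`).
#' @param twostep_amp Asymptotic two-step share after stimulus 2.
#' @param window_ms,tau_twostep_ms Passed to [two_step_ratio()].
#' @return A list of class `replenishment_breakdown` including the
#'   derived `twostep_ratio`.
#' @export
replenishment_breakdown <- function(rho2_total, rho2_replenishment,
                                    twostep_amp = 0.2, window_ms = 5,
                                    tau_twostep_ms = 4) {
  check_prob(rho2_total, "rho2_total")
  check_prob(rho2_replenishment, "rho2_replenishment")
  if (rho2_replenishment > rho2_total) {
    stop("`rho2_replenishment` cannot exceed `rho2_total`", call. = FALSE)
  }
  structure(list(rho2_total = rho2_total,
                 rho2_replenishment = rho2_replenishment,
                 twostep_amp = twostep_amp,
                 window_ms = window_ms,
                 tau_twostep_ms = tau_twostep_ms,
                 twostep_ratio = two_step_ratio(twostep_amp, window_ms,
                                                tau_twostep_ms)),
            class = "replenishment_breakdown")
}

#' Contribution of upstream replenishment to early-train release
#'
#' Computes the share of the second-stimulus release probability that
#' comes from vesicles replenished during the first interval,
#' `p2_share = (rho2_replenishment / rho2_total) * twostep_ratio`,
#' and, given the first- and second-stimulus release probabilities, the
#' percentage of `P_1 + P_2` attributable to replenishment,
#' `100 * p2_share * P_2 / (P_1 + P_2)`.  Replenished vesicles sit in the
#' replacement site, so they can only contribute through two-step
#' release, hence the attenuation by the two-step ratio.  There is no
#' replenishment contribution to `P_1` when the replacement sites start
#' full.
#'
#' @param b A [replenishment_breakdown()].
#' @param P1,P2 Release probabilities at stimuli 1 and 2, in `[0, 1]`.
#' @return A list with `p2_share` and `percent_of_sum`.
#' @examples
#' b <- replenishment_breakdown(0.460, 0.097)
#' replenishment_contribution(b, P1 = 0.88, P2 = 0.67)
#' @export
replenishment_contribution <- function(b, P1, P2) {
  stopifnot(inherits(b, "replenishment_breakdown"))
  check_prob(P1, "P1")
  check_prob(P2, "P2")
  if (b$rho2_total == 0) {
    stop("`rho2_total` is zero: the replenishment share is undefined",
         call. = FALSE)
  }
  p2_share <- b$rho2_replenishment / b$rho2_total * b$twostep_ratio
  list(p2_share = p2_share,
       percent_of_sum = if (P1 + P2 > 0) {
         100 * p2_share * P2 / (P1 + P2)
       } else {
         NA_real_
       })
}
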