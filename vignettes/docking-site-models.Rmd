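---
title: "Docking-site models and RRP estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Docking-site models and RRP estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrptools)
```

This vignette is the package's account of its science: the models it
simulates, the estimators it provides, the defaults it ships, and the
choices made where the underlying methodology left room.

## 1. The sequential docking models

Each of the `N` docking sites of a synapse is an independent release
unit.  In the two-slot **RS/DS** model a unit has a distal replacement
site (RS, some 40 nm from the membrane) and a proximal docking site
(DS) that can be occupied *simultaneously*; in the one-slot **LS/TS**
model a unit is a single slot holding at most one vesicle in a loose or
a tight state.  Time is discrete: one update cycle per action
potential, with all transition probabilities defined per
inter-stimulus interval.  The cycle order (default `"blocked"`
scheduling) is

1. **release** — an occupied DS (tight) vesicle fuses with probability
   `p_r`;
2. **docking** — RS→DS (loose→tight) with probability `r` if the DS is
   free; the arriving vesicle cannot fuse until the next AP;
3. **replenishment** — an empty RS (slot) refills from upstream with
   probability `s`; the arriving vesicle cannot dock until the next
   interval;
4. **pool refill** — each intermediate-pool vacancy refills with
   probability `r_ip`.

Initial occupancies are Bernoulli draws with probabilities `delta`
(DS/tight) and `rho` (RS; for LS/TS, loose given not tight),
independent per site and per train — trains are seconds apart in the
recordings this emulates, so no across-train state is carried.

Model capacity follows directly: fully primed and with `p_r = r = 1`,
`s = 0`, an RS/DS unit releases its DS vesicle at the first AP and its
RS vesicle at the second (`max_rrp_per_site("RSDS")` is 2), while an
LS/TS unit releases exactly one (`max_rrp_per_site("LSTS")` is 1).
This capacity difference, expressed per docking site, is what the
train-analysis estimators below are designed to measure.

### Assumptions inherited from the experimental analysis

* all sites of a synapse are statistically identical (no parallel
  heterogeneous-`p_r` structure);
* `p_r`, `r`, `s` are constant within a train (calcium entry per AP is
  stimulus-independent at this synapse type);
* transition probabilities are *per interval* and are not rescaled with
  stimulation frequency — the same parameter set is used at 100 and
  200 Hz, as in the analysis this package mirrors.  A rate-based
  conversion `p = 1 − exp(−λ·Δt)` is available
  (`rate_to_interval_prob()`) for users who prefer frequency-consistent
  semantics.

### Intra-interval scheduling

Whether a vesicle that was replenished into the RS during an interval
may *also* dock within the same interval is under-determined by the
verbal description of the original procedure.  `simulate_trains()`
therefore exposes three variants:

* `"blocked"` (default): no chaining; a replenished vesicle waits one
  interval, which matches the constraint that replenishment vesicles
  cannot advance past the RS during the first interval when `rho = 1`;
* `"chained"`: a replenished vesicle gets one immediate docking
  attempt;
* `"split_interval"`: two half-interval passes with converted
  probabilities `1 − sqrt(1 − r)`, `1 − sqrt(1 − s)`.

The variants agree exactly at the first stimulus and differ in how
upstream vesicles propagate later.  Under the potentiated parameter set
the closed-form diagnostic `rs_occupancy_before_stim2()` gives an RS
occupancy before stimulus 2 of 0.363 (native) + 0.223 (replenished)
under `"blocked"`; no variant reproduces the published occupancy
decomposition (0.460 total / 0.097 replenished), so the discrepancy is
documented rather than resolved, and the replenishment-contribution
operations take the occupancy components as explicit inputs.

## 2. Parameters and defaults

| parameter | meaning | default / typical | origin |
|---|---|---|---|
| `delta` | initial DS (tight) occupancy | 0.65 control, 0.8 4-AP, 0.9 PTP | fitted values for the three emulated conditions |
| `rho` | initial RS occupancy | 1 | fixed at 1 in the reference fitting |
| `p_r` | release probability per AP | 0.6 control, 0.9 4-AP/PTP | fitted |
| `r` | RS→DS per interval | 0.7 | fitted, shared across conditions |
| `s` | RS replenishment per interval | 0.35 | fitted, shared |
| `n_stim`, `freq_hz` | train shape | 8 APs at 100 (or 200) Hz | recording protocol |
| `n_trains` | repetitions | 5000 for simulation experiments | standard Monte-Carlo count per condition |
| `ip_size0`, `r_ip` | intermediate pool | 10–15 per 4 sites; fitted | reported fitted range |
| `tau_fast_ms`, `tau_slow_ms` | latency components | 0.47 / 4.0 ms (0.70 ms + 0.2 ms onset under K-channel block) | measured latency fits |
| slow fraction | two-step share by stimulus | ramp 0 → 0.5 over i = 1..8 | measured trend |
| sync window | synchronous release window | 5 ms | measurement convention |
| split threshold | oversized-event split | 1.7 × mean mEPSC | stated counting rule |
| `min_separation_ms` | event resolution | 0.2 ms | stated effective resolution |

`condition_params()` packages the three fitted parameter sets.

## 3. What the synthetic generator emulates — and what it does not

`generate_condition_dataset()` produces count matrices with the exact
statistics of the chosen model (the first-stimulus counts are exactly
Binomial(`N`, `δ·p_r`)) and attaches latencies post hoc: each released
vesicle draws from a fast/slow exponential mixture whose slow weight
follows the per-stimulus ramp, truncated at the inter-stimulus
interval.  This reproduces the biphasic latency histograms and the
growth of asynchronous release along the train *without* changing model
semantics — the discrete-time model itself has no intra-interval
fusion, so "slow" events are a labelling of the generator, not a model
pathway.  Consequences:

* a green latency/classification test establishes that the estimators
  handle mixture latencies correctly, not that the model predicts
  asynchronous release;
* late-train synchronous counts from the bare model are *higher* than
  real recordings (the model forces would-be asynchronous vesicles to
  stop and be counted), which is why model fitting uses stimuli 1–5 by
  default and why the intermediate-pool extension mainly improves the
  late train.

`synthesize_trace()` builds current traces from a five-parameter mEPSC
template (rise 0.15 ms, peak 50 pA, decays 1 and 8 ms, slow fraction
0.3 at 50 kHz) with multiplicative short-interval depression
`1 − d·exp(−Δt/τ_rec)` (`d = 0.3`, `τ_rec = 5` ms) and white Gaussian
noise.  These constants are *synthetic configuration values*: the
underlying saturation/desensitisation correction exists in the
experimental pipeline but its constants are not published with it, so
no claim is attached to them and the event counter shares them with the
generator in round-trip tests.  Real recordings additionally contain
mEPSC amplitude variability, non-white noise and template mismatch;
round-trip fidelity numbers here are upper bounds on real-data
performance.

## 4. Numerical choices

**Variances and covariances** use the population denominator `n`,
matching the moment-style covariance definition
`cov(S_i, s_{i+1}) = <(S_i − <S_i>)(s_{i+1} − <s_{i+1}>)>`; a
`var_denominator = "n-1"` switch exists.

**Binomial `N` fitting** minimises the summed squared deviation between
empirical relative frequencies of `k = 0..N` and the binomial pmf (the
stated objective), per candidate integer `N`, with the per-stimulus `P`
profiled out by 1-D optimisation; ties go to the smaller `N`, all-zero
data are flagged indeterminate, and a multinomial-likelihood objective
is available (selected `N` can differ on small samples).  Joint fitting
over stimuli 1 and 2 of a high-`P` condition is the recommended
protocol, because `N` is only well constrained when `P` is high.

**Variance–mean fitting** exploits that `var = m − m²/N` is linear in
`1/N`: the least-squares solution is closed form (regression of
`m − var` on `m²` through the origin), with the standard error by the
delta method.  The fit is unweighted by default — the source analysis
states no weighting — with an inverse-variance weighted variant.
Degenerate inputs (all variances zero, non-positive intercept) return a
flagged failure rather than a number.

**SMN back-extrapolation** places measurement points 5 ms after each
stimulus (when the synchronous window closes) and back-extrapolates the
late-train regression line to the *first measurement point* (stimulus
time + 5 ms), not the stimulus time; the difference is `slope × 5 ms`
and is constant across conditions.  The default fit range is the last
four stimuli; strongly depressing conditions justify 5–8, weakly
depressing ones 6–8.

**Depression decay** fits `A·exp(−(i − 3)/τ)` to the means for `i > 2`
with the asymptote fixed at zero, in stimulus-index space, then
converts via the interval (1.66 intervals at 200 Hz = 8.3 ms);
non-decaying inputs report `τ = Inf` with a flag.

**Latency fitting** is maximum likelihood on the event sample (binned
least squares available for parity with histogram-based work), on the
scale `(log τ_f, log τ_s, logit w)`; fits with `τ_f ≈ τ_s` are flagged
degenerate.

**Model fitting** uses the exact state-distribution recursion as its
default loss — it is the model's mean response computed without Monte
Carlo error, validated in the tests against brute-force enumeration of
the Bernoulli tree and against the simulator.  A Monte-Carlo loss with
common random numbers (same seed every evaluation, making the
stochastic objective a fixed smooth function) is retained as the
procedure-faithful variant.  The search is a 0.05-step grid over the
free parameters followed by box-constrained local refinement.

*Identifiability*: the five early-train means constrain four free
parameters through a flat ridge — `δ` up, `p_r` down, `r` up leave the
fit nearly unchanged, with `P_1 = δ·p_r` pinned.  At 5000 trains of a
4-site synapse the sampling displacement along this ridge is comparable
to ±0.1 per parameter, so single-dataset recovery of individual
parameters at that tolerance succeeds in only ~60 % of random
replicates (the displaced optimum has genuinely lower loss than the
truth).  The product `δ·p_r` is recovered within ±0.01 essentially
always.  The acceptance suite therefore asserts per-parameter recovery
on the median of ten replicates and the product bound per replicate.

**Event counting** deconvolves the trace with the template in the
frequency domain with Tikhonov-style regularisation (`3e-4` of the peak
spectral power), turning each event into a narrow spike; greedy peak
picking with spike subtraction gives candidate times, all amplitudes
are then refitted *jointly* by linear least squares against the raw
trace, events below threshold are pruned, and the residual is rescanned
once.  The joint refit matters: a plain matched filter overestimates
amplitudes sitting on the slow tails of earlier events (the template's
integral is large relative to its energy), producing false splits.  The
detection threshold is `4 ×` the robust (MAD) noise of the deconvolved
trace with an absolute floor of 0.3 template units; the regularisation
default is where round-trip recovery, false positives and the
split-percentage diagnostic are jointly best (99 % / 0 % / 13 % on the
shipped synthetic world).  Events closer than 0.2 ms are not resolved
temporally; they surface as oversized amplitudes and are restored by
the 1.7× split rule, which is also why the split-percentage diagnostic
is the package's undercount audit.

## 5. Known limitations

* No continuous-time calcium dynamics, no intra-interval fusion: the
  models are per-AP probability maps, and asynchronous release exists
  only in the synthetic latency layer.
* The LS/TS "tight labile" transient (a short-lived `r` increase) is
  not a model state.
* The intermediate pool couples sites within a synapse, so no
  closed-form recursion exists for it; its fitting is Monte Carlo only.
* Group-level statistics (mean ± SEM across synapses) are the user's
  job; the package analyses one count matrix at a time, and
  `run_pipeline()` iterates over conditions, not over animals.
* Published group values that depend on the recorded data (e.g. the
  back-extrapolated pool sizes of specific experiments) are not
  reproduced here; the tests assert the corresponding *properties*
  (ordering across conditions, underestimation bound, estimator
  recovery) on synthetic data instead.
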