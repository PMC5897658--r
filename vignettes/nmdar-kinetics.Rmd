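---
title: "Estimating NMDA-receptor open probability and related kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating NMDA-receptor open probability and related kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelkit)
```

## The kinetic model

At a saturating glutamate concentration (1 mM, with glycine as co-agonist)
an NMDA receptor is almost certainly doubly liganded, so agonist binding
steps can be dropped and the receptor population described by four states:

    D  <--(k_r / k_d)-->  R  <--(k_o / k_c)-->  O  <--(k_b[MK] / k_u)-->  B

D is desensitized, R closed, O open, and B blocked by MK-801, an
open-channel blocker that can only reach its site while the channel is
open. Because entry into B is gated by O, the *speed* of current loss
under MK-801 reports how often the channel is open: that is the basis of
the open-probability (P~o~) estimate. The microscopic open probability is

    P_o = 100 * k_o / (k_o + k_c)    [percent]

`simulate_occupancies()` solves the linear master equation of this scheme
for an arbitrary application protocol. Because the scheme is linear, every
constant-concentration stretch is solved *exactly* with the matrix
propagator (an eigendecomposition of the 4x4 generator, with a
scaling-and-squaring fallback); only the solution-exchange transient is
sub-stepped, at `exchange_tau/20`, with the midpoint concentration on each
sub-step. Tests verify agreement with an independent matrix-exponential
oracle to better than 1e-8 and with a stiff ODE integration to 1e-6.

Two conventions fixed package-wide: time in s, rates in 1/s,
concentrations in uM (Mg^2+^ in mM), current in pA, potential in mV;
inward current is negative. At glutamate onset all occupancy is placed in
R (receptors are liganded essentially instantly at 1 mM glutamate);
before onset the current is zero by definition.

## The two-step P~o~ procedure

**Step 1 (desensitization).** The sustained-agonist response is analyzed
for its peak `I_P`, steady state `I_SS`, and a single-exponential onset
time constant `tau_d`; then

    D   = 1 - I_SS / I_P
    k_d = D / tau_d
    k_r = (1 - D) / tau_d

`analyze_desensitization()` implements this with two windowing defaults
the source analysis leaves open, chosen here once and documented: the peak
is the extremum of the 1-ms-median-filtered current within the first
500 ms of the epoch (robust to single-sample noise), and `I_SS` is the
mean over the final 10% of the epoch (at least 200 ms). The exponential is
fitted from the peak sample to the epoch end with the offset fixed at
`I_SS`. Responses below 5 pA are treated as non-responders, and traces
that desensitize by no more than 2% are reported without rate constants
(`tau_d = NA`): the onset analysis is meaningless for an essentially flat
response, which mirrors how strongly non-desensitizing variants are
handled in practice.

**Step 2 (MK-801 block).** With `k_d`, `k_r` fixed from step 1, `k_c`
fixed at 200 1/s and `k_b` at 25 1/(uM s), `fit_po()` fits the current
during the glutamate + MK-801 epoch with `k_o` and a current scale free.
`k_c = 200 1/s` is an arbitrary anchor: in the slow-block regime only the
ratio k~o~/k~c~ is identified, which is why P~o~, not k~o~, is the
reported quantity. The initial condition is the stationary state of the
drug-free sub-scheme (the cell has equilibrated in glutamate before the
blocker arrives) and the effective MK-801 concentration rises through the
exchange filter. Block is irreversible (`k_u = 0`) by default;
`fit_po_with_unblock()` frees `k_u` for receptors showing appreciable
recovery from block, where the residual plateau current under prolonged
MK-801 reflects the block/unblock balance.

The optimizer is a coarse 25-point scan of log k~o~ over [1e-3, 1e4] 1/s
followed by golden-section refinement; the scale is profiled out in closed
form at each candidate (for `scale_mode = "free"`) or pinned to the
pre-MK-801 steady-state current (`"pinned"`). Whether the original
analysis floated or pinned the scale is not recorded anywhere we could
find; both modes are exposed and must agree within 1% on clean data
(tested). The k~u~-free variant seeds k~o~ from the irreversible scan and
starts k~u~ from three well-separated magnitudes, bounded in
[1e-8, 1e3] 1/s with a boundary warning.

```{r po-example}
rts <- rate_set(k_d = 0.17, k_r = 0.69, k_o = 27.8, k_c = 200)
prot <- application_protocol(rbind(
  protocol_epoch(0, 10, glutamate = 1000, glycine = 30),
  protocol_epoch(10, 40, glutamate = 1000, glycine = 30, mk801 = 1)
), exchange_tau = 0)
tr <- generate_whole_cell_trace(rts, prot, scale = 500, sampling_rate = 2000)
res <- two_step_pipeline(tr)
res$desens
res$po
```

## What the synthetic-data generators emulate

Every estimator in the package is validated as a closed loop: a generator
produces data from known parameters, the estimator recovers them. The
generators emulate

* macroscopic whole-cell currents from the four-state scheme, filtered by
  the first-order solution-exchange model (the measured whole-cell
  exchange constant is about 12 ms for dish-attached cells) and sampled at
  10 kHz;
* synaptic-like responses to ~5 ms glutamate pulses: an exchange-shaped
  rising phase and a mono- or bi-exponential decay (default rise constant
  1 ms, representative of fast perfusion);
* stochastic single-channel records: one channel with exponential dwell
  times, square-wave current, optional Bessel-type low-pass, Gaussian
  noise, sampled at 25 kHz;
* paired I-V tables with and without Mg^2+^ under the Woodhull block
  model; and
* Hill dose-response samples with multiplicative noise.

They deliberately do **not** model series-resistance or capacitance
artifacts, 1/f or line noise, multi-channel patches of unknown count,
sub-conductance levels, or Ca^2+^-dependent desensitization. Passing the
recovery suite therefore shows the estimators are correct and
well-conditioned under clean, known-truth conditions with realistic white
noise — not that they are immune to every pathology of a real rig. No
noise magnitude is stated in the source experiments; the defaults used in
tests (2% of peak for whole-cell work, 0.4-0.5 pA for single-channel
records at -4.5 pA amplitude) are this package's own documented choices.

Noise-free recovery checks are run with instantaneous solution exchange
(`exchange_tau = 0`) and, for the desensitization round trips, gating set
roughly 1000x faster than desensitization with a small open fraction
(k~o~ = 25, k~c~ = 5000 1/s). These are the conditions under which the
peak/steady-state arithmetic of step 1 is exact for the four-state scheme:
with a 12-ms exchange filter the measured peak of a fast-desensitizing
response (tau~d~ ~ 0.2 s) is attenuated by several percent, and with a
large open fraction part of the closed pool is diverted into O, so the
two-state reduction underlying `D = 1 - I_SS/I_P` holds only
approximately. Recovery under the realistic 12-ms filter is still tested,
with correspondingly wider tolerances.

## Dose-response and Mg^2+^-block fits

`fit_hill()` fits the logistic dose-response in two modes — normalized
agonist activation, `I = 1/(1 + (EC50/[agonist])^h)`, and steroid
potentiation, `I = I_max/(1 + (EC50/[steroid])^h)` with a free asymptote.
Internally the fit runs on log EC~50~ for conditioning, and log-scale
values are reported alongside because group comparisons in this field are
conventionally made on logEC~50~ and log h. Per-cell fitting followed by
aggregation of parameters (rather than pooling all cells into one fit) is
the supported workflow, matching how such summaries are normally tabulated.

`fit_woodhull()` fits voltage-dependent Mg^2+^ block in two stages: the
Mg^2+^-free I-V is fit by a line (giving `g0` and `V_rev`, after which
both curves are normalized to unit unblocked slope), then the blocked
curve is fit to

    I(V) = a g0 (V - V_rev) / (a + [Mg2+] exp(-b V)),   b = 2 delta F / (R T)

with `a` and `delta` free. Two interpretation points are worth making
explicit. First, `a` *is* K~d~ at 0 mV, so K~d~(V) = a e^{bV} — the only
reading consistent with reporting "K~d~(0 mV)". Second, V in mV at every
interface is converted to volts inside the exponential; `b` is stored in
1/V (for delta = 0.45 at 298.15 K, b ~ 35 1/V). `V_rev` is carried over
from stage 1 and not refloated in stage 2 — refloating it mostly trades
off against `a` on noisy data. Stage 2 uses bounded quasi-Newton
minimization from three starts across the physical delta range, because
the residual surface flattens when block is weak or voltage-independent;
fits with under 5% observed block are flagged unreliable rather than
reported. Physical constants: F = 96485 C/mol, R = 8.314 J/(mol K),
T = 298.15 K by default (room-temperature recordings).

## Synaptic-like responses and charge transfer

`fit_deactivation()` fits the decay after a brief pulse with one or two
exponentials; `auto` keeps the second component only when an
extra-sum-of-squares F-test at 0.05 says it earns its two parameters (with
a guard: a numerically perfect single-exponential fit never promotes to
two). For two components the reported constant is the amplitude-weighted
`tau_w`. Steroid effects are summarized by three numbers: potentiation
(percent amplitude increase, computed from fitted peaks rather than raw
samples, for noise robustness), deceleration (tau ratio), and the
charge-transfer factor `(1 + potentiation/100) * deceleration`, which
equals the ratio of the integrated model responses (verified against a
numerical-integration oracle in tests). Published per-cell-averaged
summary tables reproduce these factors to within about 1%, the residue of
averaging cells before multiplying.

## Single-channel idealization

`idealize_half_threshold()` detects transitions where the current crosses
the midpoint between baseline and open level, then censors open events
briefer than the dead time. The dead time defaults to the fixed constant
446 us (2.5x the rise time of the 2 kHz analysis filter); it is a
constant, not recomputed from the filter, because the digital filter here
is a rise-time-matched approximation and the censoring rule should not
drift with implementation detail. When levels are not supplied they are
estimated by 2-means on the amplitude distribution, accepted only if the
modes separate by at least 4x the within-cluster spread — otherwise the
record is treated as all-baseline rather than hallucinating openings from
noise. Amplitudes are summarized by a single-Gaussian fit (maximum
likelihood on open-event samples, edges trimmed by half a dead time to
exclude filter-rounded transitions); sub-conductance levels are
deliberately ignored. `single_channel_po()` is the plain time-average
open probability, `100 * open time / (total time x channels)` — the
simple estimator appropriate for a patch with a known channel count.

The Bessel filter itself (`filter_trace()`) is designed in-package: poles
of the reverse Bessel polynomial, normalized to the -3 dB point, bilinear
transform with pre-warping, applied as second-order sections. Its step
rise time matches the standard 0.3321/f~c~ rule within 10% (tested), and
it is documented as an approximation to an analog 4- or 8-pole filter.

## Numerical and design choices, in one place

* Propagator: exact per-segment matrix exponential; eigenbasis condition
  number checked, with a scaling-and-squaring fallback. Conservation of
  occupancy holds to ~1e-13 structurally.
* Exchange transient: first-order relaxation to the epoch target; the
  transient is integrated until the concentration is within 1e-9
  (relative) of its target, then the closed form takes over.
* All optimizers are deterministic: grid + golden section (k~o~), bounded
  L-BFGS from fixed multi-starts (k~u~, Woodhull), Levenberg-Marquardt
  from data-driven starts (exponentials, Hill).
* All randomness flows through explicit integer seeds; generators are
  pure functions of their arguments, and `run_pipeline()` records the
  seed and a config hash in its manifest.
* Problem sizes in the standard test suite: 10-s agonist epochs and 30-s
  MK-801 epochs at 10 kHz for the acceptance-grade recovery runs (2 kHz
  for fast unit tests), 2-120 s single-channel records at 25 kHz, 100
  records for the idealization agreement check.

## Known limitations

* The four-state scheme omits agonist binding, so it cannot describe
  deactivation after glutamate removal; brief-pulse responses are handled
  by the separate phenomenological exponential-decay model.
* P~o~ estimates inherit the conventions k~c~ = 200 1/s and
  k~b~ = 25 1/(uM s); a different anchor rescales k~o~ but leaves the
  fitted block time course, and hence relative comparisons, unchanged.
* In step 1 the recovered k~d~ is biased low by the open-state fraction
  (factor k~c~/(k~o~+k~c~)); at a 12% open probability that is a ~12%
  bias on k~d~ (k~r~ is unaffected). The composed two-step estimate of
  P~o~ absorbs nearly all of this (tested to 0.3 percentage points),
  because the block onset is driven by the open fraction itself.
* The time-average single-channel P~o~ assumes the channel count is
  known; NPo estimation with unknown N is out of scope.
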