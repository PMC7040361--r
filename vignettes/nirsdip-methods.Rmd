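---
title: "Methods: online fNIRS prediction and initial-dip detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: online fNIRS prediction and initial-dip detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsdip)
```

## The signal model

Each channel's chromophore series (ΔHbO or ΔHbR, arbitrary concentration
units) is modeled as a first-order ARX regression on its own lag, a lag of
the *desired HRF* input `u`, and a constant:

\[
y(k) = a\,y(k-1) + b\,u(k-1) + c_0 + e(k).
\]

`u` is the canonical HRF — a linear combination of three gamma densities —
convolved with the task boxcar and normalized to unit peak. The three
lobes are the initial dip (amplitude −1.5, shape 1.5), the main response
(amplitude 7, shape 6, peaking near 5 s), and the undershoot (amplitude
−2, shape 16); all rate parameters are 1 s⁻¹. A two-gamma HRF cannot
express the early dip; the third lobe is what makes the dip part of the
model rather than noise. The gamma time argument is interpreted in
seconds: with these shape/rate values the response peaks at a
physiological ~5 s only on a seconds scale, which resolves the otherwise
unit-free definition.

Exogenous physiological regressors are supported by the regressor builder
(`p_o > 0`) but default to zero: band-pass filtering already suppresses
most structured noise, and the online predictors track what remains.

## Online estimators

**RLS.** Standard exponentially weighted recursion with forgetting factor
λ = 0.98, initialized at `θ = 0`, `P = 10⁶ I` (a diffuse prior). The
update is `g = Pφ/(λ + φᵀPφ)`, `θ ← θ + g(y − φᵀθ)`, `P ← (P − gφᵀP)/λ`,
with explicit resymmetrization of `P` each step.

**KRLS.** Recursive kernel ridge regression on a growing dictionary. With
ridge `Rλ` (R = 10⁻⁸, λ = 0.98 by default — in this formulation λ only
scales the ridge) the inverse regularized Gram matrix `Q` and dual
coefficients `a` are updated by rank-one block recursions; the novelty of
a sample is its Schur complement `δ = Rλ + κ(φ,φ) − zᵀK`. The ALD test
admits a sample into the dictionary only when `δ > ν` (default
ν = 10⁻⁴); otherwise a dictionary-fixed update through an auxiliary
matrix `P` adjusts the coefficients without growth (the standard ALD-KRLS
reduced update). A hard dictionary cap (default 500) bounds memory and
per-step cost; at the cap the reduced update is used regardless of δ.

Kernels: Gaussian (`σ = 1`), polynomial (`c = 1, p = 1`), sigmoid
(`s = t = 1`). The sigmoid kernel is not positive semidefinite; when its
Gram loses definiteness the growing branch raises an explicit degeneracy
error rather than silently destabilizing. In practice ALD protects the
production path, because growth then requires `δ > ν` — comfortably
positive.

## Multi-step-ahead strategy

The natural q-step-ahead expression uses a regressor at time `k+q`, which
contains outputs not yet observed at decision time `k`. We therefore use
the **direct strategy**: a separate predictor per horizon is trained
online on pairs `(φ(j), y(j+q−1))`, so the prediction emitted when `y(k)`
arrives targets `y(k+q)`. Updates are delayed by q samples — a pair enters
the model only once its target has actually been observed — which keeps
the stream strictly causal (verified by a future-perturbation test). An
**iterated** strategy (one-step model, predictions fed back into the
output lag q times) is available via `strategy = "iterated"` for
comparison; it shares every other component.

Prediction quality is `%FIT = 100(1 − Σ(y−ŷ)²/Σ(y−ȳ)²)` on the held-out
test session, as printed; the rooted (NRMSE) variant is available via
`type = "nrmse"` since the system-identification literature uses both. A
constant measured series makes the ratio undefined; the fit is then
flagged degenerate (`NA`) rather than propagating NaN.

The per-sample streaming loops are compiled (RcppArmadillo). The exported
single-step functions (`rls_update`, `krls_update`, `krls_predict`) are
the reference implementation; tests pin the compiled stream to the
step-by-step path at a well-conditioned ridge. At the production ridge of
10⁻⁸ the inverse Gram can reach condition numbers of 10⁹, so two
floating-point orderings of the same algebra may differ visibly in raw
prediction values while agreeing in dictionary structure and %FIT — a
property of the recursion, not of either implementation.

## Preprocessing

Band-limiting to 0.01–0.15 Hz as a cascade of fourth-order Butterworth
low-pass (0.15 Hz) and high-pass (0.01 Hz) sections — a cascade of the two
named filters rather than a single eighth-order band-pass. Default mode is
**causal** (forward-only), because the package's claim is online
operation; zero-phase forward–backward filtering is available for offline
work. The high-pass poles sit within 2×10⁻³ of the unit circle, which
amplifies double-precision round-off to ~10⁻⁸ in any direct-form
realization; tests that probe filter algebra use tolerances above that
floor.

## Vector phase analysis and dip detection

(ΔHbO, ΔHbR) points are rotated 45° into (ΔCBV, ΔCOE); the rotation is an
isometry. Eight phases are defined by strict sign/ordering inequalities on
the four indices; points on any boundary (a measure-zero set) classify as
`none` rather than being assigned arbitrarily, and detection treats `none`
as "not a dip phase".

Calibration uses the resting prefix and the training session: `r1` is the
maximum resting-state magnitude — per channel by default, since the
defining formula is channel-generic; a `global` mode copies the most
active channel's `r1` to all channels. The most active channel maximizes
(max ΔHbO in the first training trial − max ΔHbO at rest), ties broken to
the lowest channel id. `r2 = r1 + 0.3(p1 + SD)` with `p1` and `SD` the
peak and standard deviation of that channel's trial-averaged ΔHbO trace.

Detection rule per trial, with task onset at `t = 0`:

* a candidate opens at the first sample with phase ∈ {3, 4, 5} and
  `r1 < |p| ≤ r2` inside the candidate window (default `0 < t ≤ 4` s);
* exceeding `r2` anywhere in the candidate window rejects the event as a
  false dip;
* the candidate is confirmed by a phase-7/8 sample beyond `r1` in
  `[2, 10]` s (configurable `confirm_after_s`, `confirm_end_s`).

The printed description of the timing windows is ambiguous between
"candidate within 2–4 s" and "confirm after 2–4 s"; both bounds are
exposed as parameters with the defaults above. Only phases 3–5 open
events, although phases 1–5 are all dip-like; the event records its phase
so a user can widen the rule. Reported detection times are truncated to
two decimals in human-readable output; the single-sample latency floor
`1/fs` is conventionally *rounded* (0.11 s at 9.19 Hz).

For predicted signals the detector runs on the decision-time-aligned
series: the value plotted at time `k` is the prediction of `y(k+q)` that
is available at `k`, so a dip that will occur q samples ahead is visible —
and detectable — now. Decisions are only made at post-onset samples, so
the earliest possible detection is one sample period after onset.

## The synthetic generator

`generate_dataset()` emulates the finger-tapping study design: 9.19 Hz
sampling; a 30 s resting prefix (the calibration segment — its duration is
a config knob since no canonical value exists); two sessions of six
trials (10 s task + 20 s rest, `floor(30·fs) = 275` samples per trial); 36
channels of aligned (ΔHbO, ΔHbR) pairs. Sample counts use the floor
convention per trial, with in-trial task membership decided by
`t < task_s` on the local time grid.

Per channel: ΔHbO = gain·u + dip_gain·d + noise, ΔHbR = −0.3·gain·u −
0.6·dip_gain·d + independent noise. Defaults: active montage
{17, 18, 21, 29, 30, 33} (channels repeatedly reported active over the
left motor cortex in this paradigm), HbO gain 1.0 a.u. with ±20%
per-channel jitter, dip gain 0.3. The HbR/HbO ratio of −0.3 is the
canonical antagonism; the dip mirror of 0.6 (rather than 1.0) keeps the
pure-dip trajectory off the ΔCBV = 0 boundary so it lands in phase 4
instead of on a phase edge.

The dip component `d` convolves the HRF's negative early lobe with a unit
impulse at each task *onset*, normalized to depth −1. An earlier candidate
— convolving the lobe with the full task boxcar — sustains the dip for the
whole 10 s block, contradicting the transient oxygen-extraction
phenomenon (literature peak ≈ 1.9–2.5 s); the onset-locked form matches
the physiology and is the shipped behavior.

Noise: cardiac 0.25 a.u. at 1.0 Hz, respiration 0.15 at 0.25 Hz, Mayer
0.10 at 0.1 Hz (standard physiological bands; note Mayer waves sit inside
the analysis pass-band and survive filtering, as in real data), white
noise sd 0.15 a.u., drift 0.002 a.u./s. Sub-seeds for each
channel/component derive deterministically from the master seed as
`(seed + 1000003·channel + 7919·component) mod (2³¹−1)`, so a record is a
pure function of (config, seed).

What the generator does **not** emulate: optical-density-to-concentration
conversion, motion artifacts, instrument-specific noise,
subject-to-subject variability, or nonstationary coupling between
chromophores. Passing tests on this data show the pipeline implements its
specification and behaves sensibly under realistic noise statistics; they
do not certify performance on real recordings.

## Numerical choices and degenerate inputs

* KRLS growth with `δ ≤ 0` raises a diagnostic error (non-PSD kernel or
  numerically degenerate Gram) instead of proceeding.
* Oracle-equivalence tests (recursion vs batch solve) run at ridges of
  10⁻²–10⁻³ and small-magnitude regressors: the algebraic identity holds
  for any ridge, and these choices keep both sides of the comparison away
  from round-off and keep the sigmoid Gram positive definite over the
  probe stream.
* `%FIT` on a zero-variance target errors explicitly; the fit table
  converts this to an `NA` with a `degenerate` flag.
* Angle at the phase-plane origin is undefined and returned as `NA`.
* `r1 = r2 = 0` on an all-zero record; the detector then never opens an
  event (the annulus is empty).
* Ties in `select_most_active_channel` break to the lowest channel id.

## Problem sizes used in the test suite

Unit tests run on records of 1–6 channels and single sessions. The
end-to-end benchmark used by the scientific checks and the acceptance
script is the full default configuration — 36 channels × 3575 samples ×
two chromophores, five horizons, two models (720 online fits) — which the
compiled core completes in a few seconds. The oracle equivalences use
30-sample streams (batch Gram solves) and 300–2000-sample streams
(engine equivalence, ALD behavior).

## Known limitations

* The forgetting factor in the KRLS formulation only scales the ridge; it
  does not exponentially down-weight old dictionary contributions. This
  mirrors the printed recursions; a fully forgetting KRLS (e.g.
  sliding-window or KRLS-T) is out of scope.
* The direct strategy trains a separate model per horizon; memory and
  compute scale with the number of horizons requested.
* Detection quality on predicted trajectories inherits prediction error:
  a trial can in principle be detected slightly later from predictions
  than from measurements when the trajectory sits near a threshold
  circle, although the benchmark shows no such case.
* `%FIT` compares like-for-like only when the test segment is identical;
  the package always scores on the second session by default.
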