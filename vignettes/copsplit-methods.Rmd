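---
title: "Splitting the global centre of pressure into per-foot ground reaction forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting the global centre of pressure into per-foot ground reaction forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copsplit)
```

## The problem

During bipedal stance both feet are in permanent ground contact, so the
skeleton forms a closed kinematic chain and the per-foot ground reaction
forces (GRFs) cannot be recovered from the resultant alone: a single
forceplate reports one vertical force `Fz` and one global centre of
pressure (CoP), while inverse-dynamics models of standing balance need the
force and its point of application for *each* foot. copsplit implements an
analytical resolution of this indeterminacy for quasi-static balance
exercises with prescribed foot placement, together with the signal
processing around it, a simulator that generates stance trials with known
per-foot ground truth, and a small-network regression alternative.

## The analytical split

The subject stands with the sole midlines at `y = +dy` (right) and
`y = -dy` (left), both known, with sole width `SW`. x is anteroposterior
(AP), y mediolateral (ML); the base of support spans `|y| <= dy + SW/2`.
Horizontal forces are treated as negligible (quasi-static movement,
uniaxial sensors). The split asserts:

* **AP:** each foot's CoP has the same AP coordinate as the global CoP,
  `x_left = x_right = x_global`.
* **ML:** each foot's CoP displaces within its sole proportionally to the
  global CoP's displacement within the base of support,
  `y_right = y_global * SW / (2 dy + SW) + dy` (left analogous with
  `-dy`). The scaling maps the support edge onto the sole edge.
* **Load factor:** the right foot carries the fraction
  `LF = 0.5 + y_global / (2 dy + SW)` of the vertical force,
  `Fz_right = Fz * LF`, `Fz_left = Fz * (1 - LF)`.

The inverse — the load-weighted mean of the per-foot states — recovers the
global state exactly; `reconstruct_global(split_trajectory(g)) == g` is an
algebraic identity that the test suite checks property-style over
randomised stance geometries.

Numerical choices worth knowing:

* **Bitwise force conservation.** `Fz*LF + Fz*(1-LF)` is not exact in
  floating point. `split_fz()` therefore computes the larger share by the
  product and the smaller by subtraction from `Fz`; by the Sterbenz lemma
  the subtraction is exact, and `Fz_left + Fz_right == Fz` holds bitwise
  at every sample.
* **Clamping.** Noise can push the global CoP outside the base of
  support, which would imply a negative foot load. `LF` is clamped to
  `[0, 1]` with a warning; the raw value is retained in the `LF_raw`
  column for diagnostics.
* **Invalid samples.** Samples whose total load is below the validity
  threshold (20 N by default; the moment ratio is numerically unstable
  near zero load) propagate as invalid per-foot samples. Nothing is
  interpolated across load transitions.
* **Sign convention.** The right foot sits at positive y. This matters
  when comparing left-foot ML traces, which are often displayed negated.

## Plate model and preprocessing

Each plate carries four uniaxial sensors near its corners, in the fixed
order (+x,+y), (+x,-y), (-x,+y), (-x,-y); `compute_cop()` forms
`Fz = sum(Fi)` and the CoP as the moment ratio `sum(Fi xi)/Fz`. The exact
inverse for rectangular layouts, `distribute_to_sensors()`, shares the
load with bilinear weights and backs both the simulator and
`point_load_fixture()`, a software analogue of a calibration bench that
applies known loads (12 points, 200–1000 N by default) and reports the
recovered-position error. Default plate sizes are 600 x 500 mm (lower)
and 240 x 500 mm (upper, one per foot) with a configurable 20 mm sensor
inset. Negative sensor readings (possible once noise is added; uniaxial
load cells cannot pull) are clipped at zero with a warning.

Preprocessing mirrors standard stabilometry practice:

* **Tare** (`tare()`): every recording starts with at least 3 s without
  load; the per-channel baseline mean is subtracted.
* **Zero-phase low-pass** (`lowpass_zero_phase()`): forward–backward
  Butterworth, cutoff 10 Hz. CoP dynamics in balance tasks live at
  0.5–1 Hz, so 10 Hz removes sensor noise without touching the signal.
  The per-pass order is not dictated by the problem; we default to 2
  (4th-order effective), the common choice in posturography, and expose
  it. Edge transients are controlled by odd-reflection padding of at
  least three filter settling lengths (`3 * rate / cutoff` samples) with
  steady-state initialisation; the only residual sits in the last
  fraction of a second of a recording, which `analyze_trial()` discards
  (`edge_trim`, default 0.2 s).
* **Trigger** (`trim_trial()`): trials start with a marker squat. The
  detector finds the load plateau (median over loaded samples), waits for
  the force to drop below `(1 - drop_fraction)` of it and recross upward,
  and cuts there; `drop_fraction` defaults to 0.15. A manual index mode
  overrides it.

Sampling rate is accepted as given on input; the simulator defaults to
1000 Hz, the bandwidth scale of the sensors.

## Error indicators

Per variable and foot: RMSE; NRMSE = RMSE normalised by a per-subject
constant in percent — foot length for the AP CoP, foot (ball) width for
the ML CoP, body weight for `Fz` — and the Pearson correlation. A
zero-variance signal has no defined correlation and is reported as a
missing cell rather than a number. Aggregation follows the study
convention: indicators per trial, averaged over repetitions, then over
subjects (mean +/- SD); `aggregate_metrics()` accepts any grouping so
both per-point and per-trial spreads can be inspected.

## The synthetic cohort

The human-subject recordings behind the method are not publicly
deposited, so the package carries a first-class simulator instead. A
trial reproduces the acquisition protocol — 3 s unloaded, a smooth load
ramp, a hold, a marker squat, then the exercise (30 s by default) — for
five exercise types: static hold (STC), AP sway, ML sway with
alternating load, trunk rotation (ROT, per-foot AP motion in antiphase
with near-zero global AP displacement), and random movement (RND).
Band-limited involuntary sway (sum of sinusoids in 0.5–1 Hz) rides on all
waveforms; volitional movements default to 0.25 Hz, comfortably
quasi-static. Cohorts draw body weight from Normal(76.76, 14.07) kg
truncated at +/- 2 SD and anthropometric defaults of 255 mm foot length,
100 mm ball width, `dy = SW = 100` mm — plausible adult values (feet are
roughly 2.5 times longer than wide), all configurable.

Per-foot truth is constructed first; the global trajectory is its exact
load-weighted composition; sensor channels follow from the bilinear
forward model plus Gaussian noise (sigma = 0.5 N per channel by default,
which lands the point-load bench in the 1–2 mm error range typical of
such devices). Phase transitions use C2/C3-smooth ramps so the 10 Hz
zero-phase filter passes them without measurable residue.

A single subject-level `strategy` parameter in `[0, 1]` models the
observed inter-subject variability in how the same exercise is executed.
At `strategy = 0` every trial satisfies the analytical split exactly
(this is a theorem about the construction, and a test). As `strategy`
grows, hypothesis-violating components scale in: per-foot ML excursions
shrink below what the split predicts, and per-foot AP excursions appear
that cancel exactly in the load-weighted global mean (the pattern where
the global CoP moves laterally while the individual CoPs move
anteroposteriorly). The ROT antiphase amplitude is also
strategy-scaled, so a strategy-0 cohort remains fully conforming.

What the simulator does **not** model: inertial and horizontal forces,
foot lift or slip, body-model dynamics (no inverted pendulum), sensor
drift or cross-talk, and real subjects' idiosyncratic waveforms. Passing
tests therefore demonstrate the correctness and internal consistency of
the algorithms and the qualitative error signatures of the split — not
clinical accuracy on human data.

Determinism: one master seed; per-subject and per-trial seeds are derived
by a fixed multiplicative-congruential counter scheme, so any single
trial is independently reproducible.

## The network alternative

Ten multilayer perceptrons (hidden widths (10), (50), (100), (10,10),
(10,25), (10,50), (25,50), (10,10,10), (10,10,25), (10,25,50); epoch caps
750/750/500/750/750/750/500/750/500/250) map the global sample
`(xCoP, yCoP, Fz)` to the six per-foot outputs. Hidden activation is the
tangent sigmoid, output linear, loss MSE; inputs and targets are min-max
scaled to `[-1, 1]` on training rows only; the training table is split
70/15/15 (train/validation/test) at random. Training uses
Levenberg–Marquardt with the analytic Jacobian assembled by per-output
backpropagation and chunked normal equations — feasible because these
networks have at most a couple of thousand weights. Configurations above
600 weights fall back to full-batch L-BFGS; the optimiser used is
recorded in the model metadata. "Epochs" are interpreted as maximum
optimiser iterations with validation-based early stopping (patience 6;
an improvement must exceed 0.1% relative to count). Given the seed,
training is bit-reproducible.

Design points that were genuinely open:

* **Single-sample input.** The networks see one time sample, not a
  window, consistent with predicting the distribution from the global
  CoP and force alone.
* **Row decimation.** Training rows are decimated to ~100 Hz at assembly
  and further capped (default 3000 rows, uniform stride) before fitting:
  the underlying signals live below ~1 Hz, so even 100 Hz rows are ~50x
  oversampled and a few thousand rows already tile the input domain.
* **Dataset compositions** 1–4 (AP only; ML only; STC/AP/ML; all five)
  with four of five repetitions for training and the remaining
  repetition held out. Holdout rows never touch scaling or weights; the
  suite asserts that perturbing them leaves trained weights bit-identical.
* **Selection** (`select_model()`): three elimination rounds — highest
  NRMSE on the task exercises (AP, ML), highest NRMSE on the remaining
  exercises, worst correlation — dropping 2, 3 and 4 of 10 candidates.
  The round score is the maximum over the round's exercise set of the
  mean NRMSE across the six variables (the flowchart does not pin this
  aggregation down; this choice is symmetric in the variables). Ties
  drop all tied configurations; if everything ties the lowest index
  survives with a warning.
* Network predictions do not conserve `Fz`; `predict_split()` reports
  the conservation residual per sample rather than hiding it.

## Problem sizes in the shipped checks

The acceptance checks and `ml_improvement_study()` run the full design at
sizes chosen for desk-scale runtimes: the conservation and
conforming-cohort checks use the full 10 subjects x 5 repetitions x 5
exercises at 30 s and 1000 Hz; the network replication uses 6 subjects,
20 s trials, 100 Hz training rows capped at 3000, a 10-configuration
selection grid under one seed and five seeded retrainings of the winner.
On mixed-strategy cohorts the selected network roughly halves-or-better
the analytical split's ML-exercise yCoP NRMSE, reproducing the direction
of the original comparison; on conforming trials the two approaches
agree, as they must.

## Known limitations

* The split is only as good as its assumptions; rotation-type movement
  breaks the common-AP assumption by construction, and the package's own
  checks quantify exactly that failure (an order of magnitude larger AP
  error than in AP exercises).
* The simulator's strategy model is a one-parameter blend; real
  inter-subject variability is richer, so network performance figures on
  synthetic cohorts are upper bounds of a sort — the networks can
  partially identify a synthetic subject from the weight input alone.
* Levenberg–Marquardt cost grows with the square of the weight count;
  the largest configurations are trained with L-BFGS instead, which may
  land in different (comparable-quality) optima.
* Only vertical forces are handled; horizontal GRF components and
  plane-offset corrections are out of scope.
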