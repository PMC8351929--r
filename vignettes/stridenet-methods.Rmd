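---
title: "Detecting foot-strike and toe-off from running kinematics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting foot-strike and toe-off from running kinematics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridenet)
```

## The problem

Most questions in running biomechanics — joint angles at initial contact,
contact time, duty factor, loading asymmetries — hinge on knowing exactly
when the foot strikes the ground (foot-strike, FS) and when it leaves it
(toe-off, TO). On an instrumented treadmill these instants come from the
vertical ground reaction force (vGRF): contact is wherever the force
exceeds 50 N. Force data, however, are often unavailable, and classical
kinematics-only detectors (peak accelerations, heel-marker minima) degrade
with speed, foot-strike pattern and incline.

stridenet treats event detection as a per-frame binary sequence
classification problem. A bidirectional LSTM consumes four kinematic
channels over one gait cycle and emits the probability that each motion
capture frame belongs to the contact phase; FS and TO are simply the first
and last frame of the detected contact run. Because the input features are
velocities and a joint angle — not positions — the method is insensitive to
the global coordinate system, and because the network sees the whole cycle
in both time directions it can use context on either side of each frame.

## Ground truth, and why it needs quality control

Contact labels are built from the raw vGRF at the force-plate rate:
contact is `vGRF >= 50 N` (a sample exactly at 50 N is contact). The first
and last contact frames are mapped to the *nearest* motion-capture frame
(round-half-up on exact ties, a convention we fix because "closest frame"
alone does not decide ties) and the mocap-rate label vector is 1 on
`[FS, TO]` inclusive.

Treadmill force signals misbehave near toe-off: deck bending and belt
motion can produce plateaus or small bumps exactly where the force should
fall smoothly. A cycle is therefore discarded when, inside its terminal
unloading interval — from the last downward crossing of 100 N to the next
downward crossing of 50 N — any frame-to-frame loading rate reaches
+200 N/s (1 N per frame at 200 Hz). We anchor the interval at the *last*
100 N crossing because the rule targets the unloading tail, not the
loading phase; a trace that never reaches 100 N is accepted with an
"interval absent" diagnostic, since the rule has nothing to inspect.

## The network

Two stacked bidirectional LSTM layers (400 units per direction in the full
profile), a time-distributed dense layer (200 nodes, ReLU) and a single
sigmoid output node. The cell follows the standard gate equations: forget,
input and output gates are sigmoids of affine maps of `[h_prev, x_t]`; the
cell state is `c_t = f ⊙ c_prev + i ⊙ tanh(w_c [h_prev, x_t])`; the output
is `h_t = o ⊙ tanh(c_t)`. `lstm_cell_step()` exposes exactly this
arithmetic; the batched Rcpp kernels are tested against it and against an
independent scalar-loop implementation.

The dense layer is applied per timestep (time-distributed): the output
must be a full-length probability sequence, which a single pooled dense
output could not produce.

Inputs are per-channel z-scores using the *training* set's mean and SD —
never the validation or test set's, which would leak information — then
zero-padded at the start to a fixed 200 steps (enough for one stride at
any speed we simulate: at 200 Hz the generator's longest cycle is under
1 s). Padding is skipped exactly: the recurrent state update is gated by
the sample mask, so hidden and cell states pass through unchanged at
padded steps and the loss and accuracy are computed over real frames only.
A useful side effect is that the padded prefix of the output sits at the
sigmoid midpoint (0.5) and perturbing values stored in padded positions
changes nothing, bitwise — a property the test suite asserts.

Training minimises masked binary cross-entropy with Adam (step size 1e-3,
the library-default choice), mini-batches of 200 cycles, dropout 0.5 after
each hidden layer, at most 100 epochs, early stopping once masked
validation frame accuracy has not improved for 10 epochs (best weights
restored). All randomness — initialisation (Glorot uniform, forget-gate
bias 1), shuffling, dropout — runs under one seed.

### Cross-validation protocol

Splits operate on participants, never cycles. Per dataset, 30% of
participants form the test set; the rest are dealt round-robin into five
folds, keeping fold composition representative of every dataset. Five
models are trained, each validated on its held-out fold, and accuracy is
reported as mean ± SD. The winning fold's configuration is then retrained
on all five folds for the final model. The original protocol does not say
how to early-stop this refit, which has no validation data left; we train
it for exactly the winning run's best epoch count, which is deterministic
and avoids re-using test data.

### Event extraction and its conventions

Probabilities are binarised at 0.5 (the sigmoid midpoint; exposed as a
parameter) over unmasked frames, and the *longest* contiguous contact run
supplies FS (first frame) and TO (last frame), mirroring the force-side
"first and last frame of contact" definition. The longest-run rule, rather
than first-run, makes the extractor robust to isolated supra-threshold
frames in the swing phase; ties go to the earliest run. Errors are
reported as predicted − force-derived truth in milliseconds, so negative
means early detection, and the contact-time error is identically the TO
error minus the FS error.

## Agreement statistics

Event-timing errors are quantised to the mocap frame and heavily
tied, so normal-theory limits of agreement are inappropriate. The report
therefore carries non-parametric Bland–Altman estimates: median bias with
2.5th/97.5th percentile limits, computed with linear interpolation between
order statistics (R quantile type 7 — fixed and documented because limits
can shift by up to one sample spacing between conventions). A
Kolmogorov–Smirnov statistic against a normal with the sample's estimated
mean and SD is reported alongside; estimating the parameters from the same
sample makes this a Lilliefors-style test whose p-value is conservative,
which we accept since the non-parametric estimates are what the report
carries regardless. RMSE complements the limits. Pearson correlations
(between errors and speed, foot-strike angle or incline) are banded as
trivial/small/moderate/large at |r| = 0.1, 0.3, 0.5, inclusive on the
left, with OLS slope, intercept and r² attached only for non-trivial
correlations.

## Sensitivity of joint angles to timing error

Even a perfect statistical summary does not say whether a 5 ms error
*matters*. The sensitivity analysis answers that in the units researchers
care about: for each cycle, joint (hip, knee, ankle) and event, it
compares the sagittal angle at the true event frame with the angle up to
five frames (25 ms at 200 Hz) either side. Cells are banded on their mean
absolute error: under 2° acceptable, 2–5° reasonable but requiring
consideration, above 5° unacceptable — thresholds grounded in the
test-retest reliability of marker-based kinematics. The banding statistic
is a package decision (the banding source material colours cells without
naming one); mean absolute error is monotone and matches the distribution
means shown in that style of figure. Events whose shifted frame leaves
the cycle are excluded from that offset and counted in the report.

## The synthetic gait generator

Real motion-capture datasets cannot ship with a package, so every stage is
exercised on synthetic cycles whose ground truth is known by construction.
The generator commits to a truth record first — cycle duration, exact
contact interval, speed, incline, strike pattern, foot-strike angle — and
only then renders waveforms; noise is added last and never touches the
truth record.

What it emulates, and the defaults it commits to:

* **Speeds 2.5–5 m/s** (the span of the treadmill protocols this method
  targets), with cycle duration falling from about 0.9 s to 0.6 s and duty
  factor from about 45% to 30% as speed rises; both receive physiological
  jitter and a per-participant cadence offset.
* **Strike patterns** rearfoot/midfoot/forefoot at 60/20/20 by default,
  assigned per participant (a runner's habitual pattern) by
  largest-remainder rounding; the ankle angle at contact is dorsiflexed
  (+8° to +20°) for rearfoot and plantar-flexed (−18° to −6°) for
  forefoot strikers, and rearfoot cycles carry an impact transient in
  early stance.
* **Inclines ±9°**, the widest range in the conditions we model.
* **Rates**: mocap 200 Hz, force 1000 Hz (an integer multiple, so
  event mapping between time bases is exact).
* **vGRF** as a raised-cosine active peak scaled to about 2.2–2.8
  body weights, plus the optional rearfoot impact transient; the trace is
  exactly 0 outside the committed contact interval and at least 50 N
  inside it, so 50 N labelling recovers the truth exactly. Contact bounds
  are snapped to the force-sample grid for the same reason: with off-grid
  bounds, the first force frame above threshold can round to a different
  mocap frame than the continuous truth time does, and the round-trip
  contract would be unverifiable.
* **QC violations** injected, at a configurable rate (2% in the
  acceptance runs), as a two-frame bump of +400 N/s inside the 100→50 N
  tail — twice the rejection bound, unambiguous for the filter.
* **Kinematics** as C1 piecewise half-cosine / squared-sine segments
  phase-locked to the contact interval (foot AP velocity = −belt speed
  during stance with a swing-through bump sized so the cycle mean is zero;
  foot vertical position apexed at the cycle boundary and flat in stance;
  ankle rocker from strike angle through mid-stance dorsiflexion to
  push-off plantar flexion; hip and knee curves for the sensitivity
  analysis). All segments are smooth and band-limited well below 10 Hz at
  physiological cycle durations. The sampled foot vertical velocity has
  its discrete mean removed (a sub-mm/s correction) so periodicity holds
  exactly.
* **Noise**: Gaussian, per channel, after truth construction — defaults
  0.1 m/s on velocities and 1° on angles, a moderate level for
  marker-derived signals; vGRF noise defaults to 0 so the ground truth
  stays exact (the force trace is clipped at 0 N if enabled).

What it does **not** emulate: marker-level trajectories and soft-tissue
artefact, overground gait, musculoskeletal dynamics, non-stationary
fatigue effects, or realistic force-plate noise spectra. Passing tests on
this generator therefore demonstrate that the pipeline's machinery —
labelling, masking, training, extraction, statistics — is correct and that
the architecture can learn contact phases from kinematics of this
character; they do not certify accuracy on any real laboratory dataset.

## Numerical and engineering choices

* Zero-lag filtering is a 4th-order Butterworth run forward and backward
  (the magnitude response is therefore 8th order — the usual convention
  when biomechanics reports "4th order, zero lag"), with odd reflection
  padding of about `6 × rate / cutoff` samples and mean removal before
  filtering so start-up transients act on a zero-mean signal. Velocities
  use second-order central differences (one-sided at the ends): no phase
  shift, consistent with the zero-lag philosophy. Positions and angles are
  filtered first, then differentiated.
* The LSTM forward pass and backprop-through-time are hand-written
  Rcpp/Armadillo kernels (this sequence model *is* the package's core, and
  no R deep-learning backend is assumed). Everything outside the
  recurrence — input projections, weight-gradient accumulation, input
  gradients — is hoisted into single large matrix products; tanh is
  evaluated through `2/(1+exp(−2x)) − 1`, exact up to rounding and much
  faster here than `std::tanh`. The kernels are verified three ways:
  against the scalar cell oracle, against a pure-R reference
  implementation of the full network (bitwise agreement), and against
  numerical differentiation of the loss.
* The scaled-down profile (2×64 units, dense 32) exists so the full
  pipeline trains on one CPU in minutes; the full 2×400 profile is the
  default for real use. The package's own end-to-end runs use 15
  participants × 150 cycles (~1,600 training-side cycles after QC and the
  70/30 split) and train the scaled profile for 12 epochs — by which point
  validation accuracy has plateaued above 0.99 — with fold 1 of 5 as the
  early-stopping monitor. On these conditions a typical held-out run gives
  frame accuracy ≈ 0.99, FS/TO RMSE under one mocap frame and 95% limits
  of agreement within ±2 frames; the acceptance script recomputes these
  quantities from scratch on every run rather than quoting them.
* Degenerate inputs fail loudly and early: zero-variance training
  channels, cycles longer than the 200-step window, vGRF without contact,
  splits that cannot be stratified, non-finite activations.

## Known limitations

The generator's waveforms are qualitative, not subject-specific; no claim
is made that a model trained on them transfers to real runners. The
quality-control and labelling conventions (tie-breaks, longest-run rules,
percentile interpolation) are fixed package decisions where the underlying
definitions are silent; all are documented above and exercised by tests.
Training determinism is guaranteed only up to the floating-point behaviour
of the linked BLAS. Overground running, sub-frame event interpolation and
transfer learning to new populations are out of scope.
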