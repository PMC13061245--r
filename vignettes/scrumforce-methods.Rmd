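---
title: "Estimating scrum contact forces from video kinematics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating scrum contact forces from video kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rugby scrums concentrate large impulsive forces on the front-row players'
shoulders. Direct measurement needs instrumented pressure sensors, which is
impractical in matches. `scrumforce` implements a video-only alternative:
from top-view landmark tracks of the trunk (C7 vertebra and a lumbar
point), it derives each engagement's velocity profile and trains a
sequence model to predict the full contact-force curve of the engagement
phase — from first contact (force above 10 N) to the force peak.

The package covers the complete chain: preprocessing raw tracks and force
traces into paired curves, enlarging the small paired dataset with a
generative adversarial network (GAN) and Mixup, fitting an LSTM
velocity-to-force regressor, and quantifying agreement (correlation
ranking, normalized RMSE, peak differences, Bland–Altman limits). A seeded
synthetic-trial generator with a known ground truth makes every stage
testable without measured data.

## Preprocessing model

Each trial holds 50 Hz landmark tracks for the two engaged players and a
500 Hz force trace for the instrumented shoulder. The steps, and the
choices behind them:

* **Filtering.** Landmarks are low-pass filtered at 20 Hz, forces at
  100 Hz, with a second-order Butterworth filter applied *forward and
  backward*. Zero-phase filtering is a deliberate choice: a single causal
  pass would lag the engagement by several frames and shift the apparent
  contact and peak times; the price is that the effective magnitude
  response is squared (an order-4 roll-off). The implementation pads by
  odd reflection and starts each pass at steady state, so constants pass
  through exactly and step transients at the window edges are suppressed.
  A 20 Hz cutoff at 50 Hz video is 80% of Nyquist; it is allowed but
  warned about, because attenuation near the passband edge is mild and
  mostly reflects the digital filter's zero at Nyquist.
* **Velocity.** The C7–lumbar midpoint is differentiated with central
  differences on interior frames and one-sided differences at the ends,
  times the frame rate; the speed is the Euclidean norm of that
  derivative. The engagement velocity of a pairing is the element-wise
  mean of the two players' speeds.
* **Segmentation.** The analyzed window runs from the first force sample
  above 10 N to the global force maximum, first occurrence on ties
  (deterministic). Windows are closed intervals with 1-based indices —
  the natural indexing of the host language. A window that degenerates to
  a single sample is rejected with a distinct error rather than
  interpolated: a one-point "curve" carries no shape.
* **Rate synchronization.** The window is found in force time (500 Hz)
  and its start/end times are mapped to the nearest video frame. Both
  channels are then *independently* time-normalized to 101 points by
  linear interpolation over normalized time [0, 1], which makes the 10:1
  rate mismatch irrelevant downstream and preserves the first and last
  samples exactly — so the normalized force curve still ends at its peak.
* **Cleaning.** Trials whose peak velocity leaves [2.5, 4.5] m/s or peak
  force leaves [1, 4] kN are dropped as physiologically implausible or
  technically faulty. Bounds are inclusive (the weaker reading of
  "within the range"), cleaning is applied after filtering, and the
  rejection log records each violated rule.

## GAN augmentation

The generator maps a 50-dimensional latent vector through a dense layer
read as a 26-step × 128-channel tensor, two stride-2 transposed
convolutions (kernel 5, zero padding; 64 then 2 filters; batch-normalized;
SELU then tanh activations) up to 104 × 2, and a final dense tanh layer of
202 units — one velocity curve and one force curve of 101 points each,
packed velocity-first. This is the only reading of a "26x128 dense layer
followed by two stride-2 convolutions ending in 202 outputs" that is
self-consistent: 26 upsamples to 52 and then 104 time steps, and
2 × 101 = 202. The discriminator reads the pair as a 101 × 2 sequence
through two stride-2 convolutions (64, 128 filters, LeakyReLU, 40%
dropout) and a sigmoid unit.

Training choices that the architecture alone does not pin down, and that we
fixed as standard adversarial practice: the non-saturating binary
cross-entropy, one discriminator step per generator step, Adam at 1e-3
with first-moment decay 0.5, and one-sided label smoothing (real targets
0.9). Curves enter the tanh range after per-channel max-abs scaling
computed on the GAN's training set and stored with the model; generation
inverts the scaling, so generated force peaks can never exceed the largest
training magnitude. Tiny negative velocities permitted by the tanh output
are clipped to zero (speed is a magnitude). The default budget is 3000
epochs at batch 32, chosen to converge on desk-scale datasets of tens to
hundreds of pairs; all budgets are configurable, and one seed controls
weight initialization, latent draws, batching and dropout bitwise.

Generation fidelity is reported as the mean Pearson correlation and RMSE
between each generated curve and its *best-correlated* measured curve, per
channel. The matching rule is recorded in the report: it rewards
generators whose curves lie inside the measured family without requiring a
one-to-one pairing, and it is the quantity our acceptance checks
threshold.

**Mixup.** New pairs are formed as 0.5/0.5 averages of two distinct pool
members. `build_augmented_dataset()` mixes the GAN pool by default; the
end-to-end pipeline additionally admits the measured pairs into the Mixup
pool — the textbook Mixup formulation, in which real examples are mixed.
This matters in practice: a partially collapsed generator can lose the
measured amplitude spread, and mixed measured parents restore it while the
training set still contains no raw measured pair. A constant coefficient
keeps the mixtures physically meaningful intermediate engagements;
convexity guarantees the mixed force curve stays inside the parents'
pointwise envelope.

## The LSTM regressor

The default model — two LSTM layers of 128 and 64 cells followed by a
per-time-step dense ReLU unit — is the published outcome of a grid search
over 1–3 layers, {32, 64, 128} cells and learning rates
{0.001, 0.002, 0.01}; the package's `grid_search()` enumerates that
27-point space with k-fold cross-validation (default 5 folds, the
conventional count) using one shared cell width per candidate, since the
stated space cannot produce mixed widths. The published mixed-width
[128, 64] model is nevertheless the default configuration, accepted as the
published final architecture.

Both channels are normalized by the maximum absolute value over the entire
training dataset; the constants are persisted in the fitted model and
re-applied verbatim at prediction time. Normalization happens *inside*
`train_predictor()` and `predict_force()`, so double scaling is impossible
by construction. Training minimizes mean squared error on the scaled force
curves with Adam (default rate 0.002, batch 32, at most 1000 epochs) and
early stopping: when validation loss has not improved for `patience`
epochs (default 50) training halts and the best epoch's weights are
restored. The ReLU head guarantees non-negative forces; its bias is
initialized at 0.5 — the scale of the positive, max-abs-scaled force
targets — because at initialization the LSTM output is nearly
input-independent and a zero-initialized scalar head can start dead
(all pre-activations negative, zero gradient). Sequences are fed in
natural time order, start to peak; the engagement is causal and no
bidirectional context is used.

## Evaluation

Per trial: Pearson r between measured and predicted force curves, RMSE in
newtons, absolute peak difference, and percentages of both normalized by
the trial's measured maximum. Correlations are ranked poor / moderate /
good / excellent with boundaries 0.5, 0.75, 0.9; upper endpoints belong to
the lower band (0.75 is moderate, 0.9 is good), a deterministic resolution
of band notations that print overlapping endpoints.

Bland–Altman analysis of peak forces uses differences
`predicted − measured` — a positive bias means overestimation — with
limits of agreement at bias ± 1.96 · SD (n−1 denominator, the standard
limits-of-agreement practice) and per-technique sub-results on label
subsets. Grouped reports (by engagement technique or by shoulder) give
mean ± SD of each metric, with percentage columns recomputed against the
maximum force across the *group's* measured curves rather than per-trial
maxima, so that group percentages share one normalization basis.

## The synthetic generator

`simulate_pair()` emulates the statistical structure of measured
engagements, not their biomechanics: a smooth unimodal velocity bump with
peak drawn uniformly from [2.5, 4.5] m/s; contact building as the
normalized cumulative squared speed `s(t)`; and a noise-free force

```
f(t) = floor + (F_peak − floor) · s(t)^γ,   F_peak = (a · v_peak + b) · technique_scale
```

with defaults a = 850 N/(m/s), b = −600 N, γ = 1.5, a 12 N contact floor
just above the 10 N detection threshold, and `technique_scale` = 0.8 for
PreBind (pre-bound engagements produce lower impact forces). The realized
"measured" force multiplies the rise by a trial-level log-normal factor
(SD 0.25), truncated so peaks stay inside the cleaning ranges; this makes
the velocity–force association positive but noisy — a moderate
correlation, not a deterministic link — which is what measured
distributions show. The slope/intercept place deterministic peaks within
roughly 1.2–3.2 kN across the velocity range, safely inside [1, 4] kN.
Because the force is a deterministic functional of the velocity curve plus
technique and noise, the generator can expose the exact ground truth, and
predictor tests can measure error against it rather than against the noisy
realization.

`simulate_raw_trial()` inverts a pair into raw signals: landmark tracks at
50 Hz whose midpoint integrates the velocity curve (trapezoid rule, so
central differences recover the speed to second order), constant
C7/lumbar offsets plus optional i.i.d. positional jitter, and a 500 Hz
force trace with a sub-threshold pre-contact segment and a post-peak
decay. Engagement durations are quantized to the video frame grid so the
round trip is not blurred by window rounding. With zero jitter the full
preprocessing chain recovers the source force peak within 1%; the velocity
peak is recovered within 7% — central differences at 50 Hz flatten a
sharp engagement bump by about v″·Δt²/6 and the near-Nyquist landmark
filter smooths it further. These tolerances were measured once on the
noise-free chain and frozen in the tests; they are properties of the
measurement chain being emulated, not implementation slack.

What the generator does **not** emulate: pose-dependent force directions,
coupling between the six simultaneous shoulder contacts, pack-mass
effects, sensor drift or saturation, and tracking artefacts beyond white
positional jitter. Passing the package's tests therefore demonstrates
that the pipeline recovers a known kinematics-to-force mapping under
realistic ranges and noise — it does not certify accuracy on real match
data.

## Problem sizes and budgets used by the test and acceptance runs

Desk-scale rehearsal sizes, chosen as package defaults for reproducible
runs on a single CPU: GAN fidelity is assessed on 200 synthetic pairs with
a reduced budget of 150 epochs; the end-to-end run uses 60 simulated
trials, 400 GAN + 200 Mixup pairs (measured parents admitted to the Mixup
pool), an 80/20 split of the augmented set, and 50 LSTM epochs (batch 64,
patience 15) on the published [128, 64] architecture. The end-to-end GAN
trains with batch 16 for 1000 epochs: at fixed wall time, many small
adversarial updates preserve the generated amplitude distribution much
better than few large ones, whose generators tend to collapse onto a
narrow peak-force band. The identity check uses a small network and the
0.01 learning rate from the grid, which converges much faster on that
smooth task; the parameter-recovery check keeps the published 0.002 —
at 0.01 the full-size regressor can overshoot early and permanently kill
the ReLU output head (a known failure mode of ReLU units; the positive
bias initialization protects the start of training, not every update). The end-to-end protocol mirrors the
train/test discipline of the measured study: the regressor trains only on
augmented pairs and is tested only on (simulated-)measured pairs, enforced
structurally by checking provenance labels, never by convention.

## Known limitations

* The GAN is trained fresh per dataset and its sample diversity at small
  epoch budgets is narrower than the measured distribution (amplitude
  spread shrinks before shape diversity does); the predictor inherits any
  such narrowing through the augmented training set.
* The engagement-phase model stops at the force peak; sustained pushing
  after the peak is out of scope.
* Technique labels are metadata only — the regressor sees velocity alone,
  so systematic technique effects on amplitude (e.g. PreBind's lower
  peaks) are an irreducible error source unless they are expressed in the
  velocity curve.
* Pixel-to-metre calibration and landmark identification are assumed done
  upstream; the loaders consume metric coordinates.
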