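# scrumforce

Estimation of per-shoulder contact forces in rugby scrum engagements from
top-view video kinematics.

## The problem

Scrum engagements load the front-row players' shoulders with impulsive
forces of 1–4 kN. Measuring them directly requires pressure sensors that
players cannot wear in matches. This package implements a video-only
pipeline: from 2D tracks of two trunk landmarks per player (C7 vertebra
and a lumbar point, 50 Hz top view), it computes each engagement's
velocity profile and predicts the full contact-force curve of the
engagement phase with a trained sequence model.

For an engagement between a pair of players, the preprocessed record is a
pair of 101-point curves on normalized time *t* ∈ [0, 1], from first
contact (force > 10 N) to the force peak:

* *v(t)* — mean trunk-midpoint speed of the two players (m/s), from
  zero-phase Butterworth-filtered landmarks (20 Hz cutoff) differentiated
  by central differences;
* *F(t)* — contact force (N), filtered at 100 Hz, windowed so that
  *F*(1) = max *F*.

Because measured datasets are small (tens of trials after cleaning to
peak ranges 2.5–4.5 m/s and 1–4 kN), the training set is enlarged with

* a **convolutional GAN** (latent dim 50; generator dense 26×128 → two
  stride-2 transposed convs, 64 then 2 filters, SELU/tanh, batch-norm →
  dense 202 tanh; discriminator two stride-2 convs 64/128, LeakyReLU, 40%
  dropout → sigmoid) generating new (v, F) pairs, and
* **Mixup**: 0.5/0.5 convex combinations of pool members.

The regressor is a stacked **LSTM** (default 128 and 64 cells, the
outcome of a 3×3×3 grid search over layers/cells/learning rate) with a
per-time-step ReLU output unit, trained with Adam (0.002) on max-abs-scaled
curves, early stopping, and an 80/20 train/validation split of the
augmented data; testing uses only measured pairs. Agreement is reported as
Pearson r (ranked poor < 0.5 < moderate < 0.75 < good < 0.9 < excellent),
RMSE and peak difference with percentages normalized to the measured
maximum, and Bland–Altman bias ± 1.96 SD on peak forces.

All of this — including the GAN and LSTM, implemented from scratch on
RcppArmadillo kernels with finite-difference-verified gradients — runs on
a single CPU with no deep-learning framework.

## Worked example

A seeded synthetic-trial generator emulates measured engagements (velocity
peaks 2.5–4.5 m/s, monotone force rises ending at 1–4 kN peaks, lower
PreBind forces, noisy positive velocity–force association) with a known
ground-truth mapping, so the whole pipeline can be exercised without any
measured data:

```r
library(scrumforce)

trials <- simulate_dataset(sim_config(n_trials = 60, seed = 11))
res <- run_end_to_end(trials, pipeline_config(
  gan = gan_config(epochs = 2000, batch_size = 16, seed = 1),
  rnn = rnn_config(epochs = 50, batch_size = 64, patience = 15, seed = 1),
  n_gan = 400, n_mix = 200, seed = 1))
print(res)
```

```
<scrumforce_run> 57 measured pairs (3 rejected), 600 augmented
  agreement vs measured: mean r 0.992, mean nRMSE 16.7%, mean peak diff 22.3%
  agreement vs ground truth: mean r 0.992, mean nRMSE 13.5%
  Bland-Altman: bias -151.2 N, LoA [-1515, 1213] N
```

The run takes about 8 minutes on one CPU. Reading the output: 3 of the 60
simulated trials fall outside the plausibility ranges after filtering and
are cleaned away. The LSTM — trained only on the 600 GAN/Mixup pairs,
never on a raw measured pair — predicts the held-out measured force
curves with mean correlation 0.99 ("excellent" band). Against the
*noise-free ground truth* the mean normalized RMSE is 13.5%; against the
noisy realizations it is larger (16.7%), as it must be, since the
trial-level amplitude noise (SD 25%) is unpredictable from velocity. The
wide Bland–Altman limits reflect that same irreducible peak noise; the
bias (−151 N on ~2.4 kN peaks, a mild underestimation) is small against
the limits' width.

Per-trial records, grouped tables and the Bland–Altman object are in
`res$records`, `res$by_technique`, `res$by_shoulder`, `res$bland_altman`.

A thin command-line front end (`exec/scrumforce`) exposes the stages as
`simulate`, `preprocess`, `augment`, `train`, `predict`, `evaluate` and
`run-all` over a plain CSV+JSON interchange dialect (see
`?write_pair_dataset`); any external deposit of engagement trials can be
used by exporting it to that dialect.

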