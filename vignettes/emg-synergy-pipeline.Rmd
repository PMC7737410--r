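---
title: "Decomposing multi-channel forearm EMG: ICA, non-negative synergies, and direction decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing multi-channel forearm EMG: ICA, non-negative synergies, and direction decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Surface EMG recorded from a dense forearm grid mixes the activity of many
muscles with line interference, electrode noise, and crosstalk. Superficial
muscles project onto a handful of nearby electrodes; deep muscles project
diffusely across the cross-section of the forearm, so their contribution is
easily buried. `emgsynergy` implements a two-stage decomposition pipeline
for eight-direction index-finger movement decoding:

1. **ICA** (`X = A S`) separates the 95-channel EMG into independent
   components, rejecting components with white-noise characteristics;
2. **non-negative matrix factorization** (`E = T M`, HALS updates) of the
   pseudo-joint-torque envelopes — of either the EMG channels or the
   retained ICs — yields muscle synergies: fixed non-negative channel
   weightings `M` driven by shared activations `T`;
3. synergies extracted separately at two elbow postures (0° and 90°) and
   from the pooled data are clustered into **synergy modules** by their
   mutual scalar product (SP) under UPGMA, and each synergy's **preferred
   direction** (PD) and **tuning weight** `W` are estimated by cosine
   tuning;
4. a compact **CNN** classifies movement direction from four input
   representations (EMG-input, IC-input, EMG-synergy, ICA-synergy) in both
   the extrinsic (screen) and intrinsic (forearm) coordinate frames.

Because the kind of recording this targets is not generally available, the
package ships a first-class synthetic generator with full ground truth;
every stage is tested against quantities the generator planted.

# The synthetic recording

`simulate_dataset()` emulates the recording design end to end: 96
electrodes on a regular 12 × 8 cylindrical grid along the forearm (the last
grid channel serves as the ground reference and sits on the hand dorsum),
8 target directions at 45° spacing × 2 elbow postures × `n_reps`
repetitions, EMG sampled at `fs_emg` and a 2-D cursor at 100 Hz.

Each planted source is cosine-tuned: its activation level for a trial is
`max(0, a0 + W cos(θ_eff − PD))`, ramped on after the onset latency. For
intrinsic-frame sources, `θ_eff` is the screen direction rotated by the
elbow angle, which is the mechanism that makes intrinsic-frame relabeling
profitable downstream. The default source set operates in the linear
tuning regime (`a0 ≥ W`), so the clipping in `max(0, ·)` is inactive and
planted `(a0, W, PD)` are exactly recoverable from noiseless envelopes —
a closed-loop property the test suite asserts. A consequence worth knowing:
in this regime every tuned envelope lies in the span of
{gating, gating·cosθ, gating·sinθ}, so the envelope matrices of *both*
representations have an essentially rank-3 tuned subspace, and the
synergy-count selection typically returns the smallest candidate rank for
both. The large EMG-versus-ICA synergy-count gap seen in real recordings
reflects envelope diversity this generator deliberately does not model.

The carrier of each source is Gaussian noise band-passed to 20–450 Hz
(upper edge clamped to `0.45 fs`) and scaled to unit mean rectified
amplitude, so the mean rectified source signal reproduces the tuned level.
Three noise processes are added:

* **line interference**: a common 50 Hz sinusoid with random per-channel
  gain (`line_amp`, default 0.05 of clean RMS);
* **white sensor noise**, calibrated so the realized clean-to-noise power
  ratio equals `snr_db` (default 10 dB);
* **baseline noise**: per-channel broadband carriers with slowly varying
  random amplitude (`baseline_amp` 0.2, bandwidth 0.5 Hz), emulating
  nonstationary electrode/skin noise.

The ground electrode carries no muscle signal and its noise is scaled by
`ground_noise_scale` (0.5) — the actively driven ground is the least
vibrating point, which is exactly how the preprocessing stage finds and
removes it. What the generator does **not** model: volume conduction with
realistic tissue geometry, motor-unit discharge statistics, fatigue,
amplitude cross-correlations between muscles, or electrode impedance
drift. Passing tests therefore certify algorithmic correctness and
direction-of-effect behavior, not performance on real recordings.

# Preprocessing

`apply_filters()` applies a 4th-order Butterworth band-pass (10–1000 Hz;
the upper edge is clamped to `0.45 fs` at reduced sampling rates) plus a
2nd-order IIR notch at 50 Hz (Q = 35), both forward–backward for zero
phase. Plain forward–backward filtering leaves edge transients that
dominate narrow-band attenuation measurements, so filtering uses
odd-reflection padding; the realized 50 Hz attenuation is then far beyond
the 26 dB contract. The ground channel is identified as the channel of
minimum standard deviation (ties to the lowest index) and removed, leaving
95 channels.

Movement onset is cursor-defined: the first sample whose Euclidean
displacement from the trial-start position exceeds 2% of the final
displacement. Classification inputs are epoched to exactly 25 samples at
50 Hz spanning `[onset − 0.2 s, onset + 0.3 s)` (half-open, so
0.5 s × 50 Hz = 25). Intrinsic-frame relabeling rotates Elbow-90 direction
labels 90° clockwise — two index steps, with the sign configurable
(`rotation_sign`) because the screen's direction-numbering convention is
itself a convention.

Downsampling to 50 Hz destroys a 20–450 Hz carrier outright (the
anti-alias filter keeps only < 22.5 Hz), so the EMG-input and IC-input
representations are **rectified before downsampling**: what the classifier
sees is the activity envelope at 50 Hz. Synergy activations are 5 Hz
envelopes and unaffected by this choice.

# Envelopes, HALS, and how many synergies

`to_pseudo_torque()` builds the NMF input: each signal is divided by its
mean rectified amplitude over the whole dataset, rectified, low-passed by
a zero-phase 2nd-order Butterworth at 5 Hz, and clipped at zero.
Envelopes are factorized at 50 Hz (lossless for a 5 Hz signal and an
order-of-magnitude cheaper than the native rate).

`hals_nmf()` minimizes `‖E − TM‖²_F` under non-negativity with
hierarchical alternating least squares. Numerical choices: non-negative
uniform initialization scaled by `sqrt(mean(E)/s)` (which makes the
trajectory — and hence the selected rank — exactly invariant to scaling of
`E`); an `1e-12` guard in the update denominators (the damped update is a
partial step toward the block minimizer, so monotonicity is preserved); a
dead synergy row is re-initialized randomly once with its activation
column zeroed (objective unchanged, so the trace stays non-increasing) and
is afterwards allowed to die; rows of `M` are scaled to unit maximum with
the scale absorbed into `T`.

VAF is uncentered, `1 − SSE/‖E‖²`, the muscle-synergy convention (a
per-signal variant is exposed via `vaf(..., per_signal = TRUE)`).
`select_rank()` picks the smallest candidate satisfying **both**
VAF > 0.9 and a plateau-linearity condition: the mean squared error of an
OLS line fitted to the VAF curve over ranks ≥ the candidate must be below
1e-4. The line is fitted on the plateau side because that is the side
whose straightness certifies that additional synergies only absorb noise;
with fewer than 3 remaining points the MSE is defined as 0 (a line fits
them exactly). Each rank is fitted from several seeds plus a warm start
from the previous rank padded with a near-zero synergy, which guarantees a
non-decreasing best-VAF curve. Desk-scale candidate ranges are 3–20 (EMG)
and 3–12 (IC); the full-scale ranges 3–30 / 3–15 are a config change.

# ICA stage

`fit_ica()` is symmetric FastICA with the log-cosh contrast on whitened
data, restarting with an incremented seed on non-convergence. The
convergence tolerance defaults to 1e-4 — the customary FastICA setting —
because tighter values sit below the finite-sample noise floor whenever
near-Gaussian components are present. Components follow a deterministic
sign convention (largest-magnitude mixing weight positive) and are ordered
by mixing-column energy. The default component count is the numerical rank
of the whitened data; the pipeline configuration caps it at 20 at desk
scale, which is the package's own choice for a 95-channel recording whose
informative subspace is far smaller.

White-noise component rejection is automated (the field often does this by
eye): a component is excluded when its spectral flatness exceeds 0.6 *and*
the lag-1 autocorrelation of its rectified signal falls below 0.2.
Flatness is evaluated **within the preprocessing passband** — after a
10–460 Hz band-pass, everything is non-flat over the full Nyquist range,
so judging flatness in-band is what makes filtered white noise
recognizable. Both thresholds are configuration values and the manifest
records that the criterion is a stand-in for expert screening.

# Modules, tuning, typing

Synergies from Elbow 0, Elbow 90, and the total dataset (all at the rank
selected on the total dataset) are compared by scalar product
`e_i·e_j/(‖e_i‖‖e_j‖)` and clustered by UPGMA (average linkage on
`1 − SP`), cutting so that merges require average inter-cluster SP
strictly above 0.75. The UPGMA cut, not mere pairwise similarity, decides
borderline triples; `hclust` is the engine and an exhaustive agglomeration
oracle verifies it in the tests.

Cosine tuning fits `m(θ) = a0 + a1 cos θ + a2 sin θ` to the 8 per-direction
mean amplitudes; on equally spaced angles the design is orthogonal and the
coefficients are exact discrete Fourier terms. `W = sqrt(a1² + a2²)`
(a squared variant is available), and `m` is divided by its maximum before
the regression so `W` is a dimensionless modulation ratio (mean- and
un-normalized variants are options). PDs are undefined below a tuning
floor. Within a module, Elbow-90 PDs are compensated by 90° clockwise and
the PD error is the mean absolute circular deviation from the circular
mean (resultant-vector mean; minimal angular distances).

Module typing compares the weight-weighted spread of electrode positions
along the forearm axis against the spread around the circumference, each
normalized by its grid extent: axial ≥ circumferential ⇒ "parallel"
(the superficial-muscle signature), otherwise "local" (cross-sectional,
the deep-muscle signature). The circumferential coordinate is treated
linearly on its 0–315° grid, which slightly penalizes modules wrapping
across 360°; IC-space synergies are first mapped to channels through the
magnitudes of the retained mixing columns.

# Classification

The classifier is intentionally small: one 3 × 3 convolution with 32
filters and ReLU over the channels × 25 image, 2 × 2 max pooling
(degrading to 1 × 2 when a synergy input has too few rows), a 64-unit
dense ReLU layer, and softmax over 8 directions; Adam (1e-3), minibatch
32, early stopping on a 10% validation split with patience 6, at most 30
epochs (capped at 20 with a warning below 20 trials per class). It is
implemented directly on matrix primitives (im2col); backpropagation is
verified against finite differences in the tests. Features are z-scored
per (channel, time) cell using training-fold statistics only. Fivefold
cross-validation is stratified jointly by direction × posture on the
extrinsic labels, so extrinsic and intrinsic runs use identical splits and
fold-accuracy contrasts are paired. Fold accuracies are compared with
Welch t-tests.

# Orchestration and reproducibility

`run_pipeline(default_config(seed))` executes
simulate → preprocess → ica → synergy → modules → classify, storing every
stage's outputs in one container object; `validate_container()` checks
shapes and invariants, and a manifest records the config, per-stage seeds
and wall times. One global seed derives per-stage seeds by hashing the
stage name, so any stage re-runs identically; resuming from a container
recomputes only missing stages. The container is a native R object
(persist with `saveRDS()` if needed).

Desk-scale problem sizes, used by the tests and the acceptance script:
1024 Hz EMG, 10 repetitions per direction × posture cell (160 trials,
~400 s of recording), 20 ICA components, candidate synergy ranks 3–20 /
3–12. Full-scale settings (2048 Hz, 80 repetitions, ranks to 30) are plain
configuration changes.

# Known limitations

* The generator's linear-regime tuning keeps the planted envelope subspace
  low-rank, so synergy-count *differences* between representations (as
  opposed to orderings of accuracy, tuning weight, and PD consistency) are
  not a property this synthetic design can exhibit.
* The white-noise rejection rule is a two-threshold stand-in for expert
  component screening.
* Module typing ignores circumferential wraparound.
* The CNN is a fixed small architecture without hyperparameter search;
  with very few trials per class its accuracies have high fold-to-fold
  variance.
* Amplitude-based envelope representations discard all spectral detail
  above 25 Hz at the classification stage.
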