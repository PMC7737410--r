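# emgsynergy

Separating overlapping superficial and deep muscle activity in dense
surface EMG, and decoding movement direction from the result.

A 96-electrode forearm grid records index-finger movements toward eight
targets at two elbow postures. Each channel mixes several muscles with
line interference, electrode noise, and crosstalk, so single-muscle
activity — especially from deep muscles, which project diffusely across
the forearm cross-section — is not directly observable. `emgsynergy`
implements a sequential blind-source-separation pipeline:

* **ICA**, `X = A S`: symmetric FastICA (log-cosh contrast) on the 95
  retained channels, followed by automated rejection of components with
  white-noise characteristics (in-band spectral flatness > 0.6 and
  rectified-signal lag-1 autocorrelation < 0.2);
* **muscle synergies**, `E = T M` with `T, M ≥ 0`: hierarchical
  alternating least squares (HALS) NMF of pseudo-joint-torque envelopes
  (mean-normalized, rectified, 5 Hz zero-phase Butterworth low-pass),
  with the synergy count chosen as the smallest rank with uncentered
  VAF > 0.9 whose VAF curve is linear beyond it (plateau line-fit
  MSE < 1e-4);
* **synergy modules across postures**: scalar-product similarity
  `e_i·e_j/(‖e_i‖‖e_j‖)`, UPGMA clustering with modules formed above
  SP = 0.75, cosine tuning `m(θ) = a0 + a1 cos θ + a2 sin θ` giving each
  synergy a preferred direction `PD = atan2(a2, a1)` and tuning weight
  `W = sqrt(a1² + a2²)`, with Elbow-90 PDs compensated 90° clockwise;
* **direction decoding**: a compact CNN (3×3 × 32 filters, 2×2 max-pool,
  dense 64, softmax 8) under stratified fivefold cross-validation,
  compared across four inputs — EMG-input, IC-input, EMG-synergy,
  ICA-synergy — in extrinsic (screen) and intrinsic (forearm) frames.

Because such recordings are not generally available, the package includes
a fully ground-truthed synthetic generator (`simulate_dataset()`): tuned
superficial sources with local electrode footprints, deep sources with
cross-sectional footprints, line/baseline/white noise, and cursor
trajectories — every downstream stage is testable against planted truth.

## Worked example

```r
library(emgsynergy)

ct <- run_pipeline(default_config(seed = 1))

sum(ct$ica$retained_mask)          # ICs kept after white-noise rejection
#> [1] 6
c(ct$synergy$emg$selected_rank,    # synergy counts (EMG vs ICA input)
  ct$synergy$ica$selected_rank)
#> [1] 3 3
c(ct$modules$emg$mean_w, ct$modules$ica$mean_w)
#> [1] 0.3144138 0.4714774
c(ct$modules$emg$mean_pd_error_deg, ct$modules$ica$mean_pd_error_deg)
#> [1] 30.61705 19.81555
ct$classify$summary
#>     input_type     frame mean_accuracy n_inputs
#> 1          emg extrinsic       0.23750       95
#> 2          emg intrinsic       0.68750       95
#> 3           ic extrinsic       0.35000        6
#> 4           ic intrinsic       0.98125        6
#> 5  emg_synergy extrinsic       0.22500        3
#> 6  emg_synergy intrinsic       0.51250        3
#> 7  ica_synergy extrinsic       0.45000        3
#> 8  ica_synergy intrinsic       0.99375        3
```

Reading these numbers: of 20 extracted components, 6 survive white-noise
rejection — the planted muscle sources. ICA-synergy modules are more
sharply direction-tuned than EMG-synergy modules (mean tuning weight 0.47
vs 0.31) and point more consistently across postures (mean PD error 19.8°
vs 30.6°). Decoding from the intrinsic frame beats the extrinsic frame
for every input type (the planted sources are muscle-fixed, so rotating
Elbow-90 labels 90° clockwise aligns their tuning across postures), and
ICA-based synergies decode markedly better than EMG-based synergies
(0.99 vs 0.51) from equally few inputs.

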