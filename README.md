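# progseg

Progressive, prior-guided auto-segmentation of serial 3D images for
fractionated adaptive radiotherapy (ART).

In online ART a fresh cone-beam CT (or a synthetic CT derived from it) is
acquired at every treatment fraction, and the targets and organs-at-risk
must be re-contoured while the patient waits. Conventional auto-segmentation
treats each fraction as an unrelated image and repeats the same mistakes
session after session, even though clinician-approved contours of the *same
patient* exist from every previous fraction. `progseg` implements a
sequence-aware model for this setting:

* **LSTM-UNet** — a 3D U-Net whose skip connections each carry a
  convolutional LSTM unit. The input at fraction *t* is a 3-channel stack
  (previous image, previous contours as a label map, current image); the
  per-level states (h(t), c(t)) evolve with

      i = σ(W_xi∗x + W_hi∗h + b_i)   f = σ(W_xf∗x + W_hf∗h + b_f)
      o = σ(W_xo∗x + W_ho∗h + b_o)   g = tanh(W_xg∗x + W_hg∗h + b_g)
      c(t) = f⊙c(t−1) + i⊙g          h(t) = o⊙tanh(c(t))

  (∗ a 3×3×3 convolution), accumulating a multi-resolution memory of the
  patient across fractions; memory is zeroed at patient boundaries. The
  cell state c(t) feeds the decoder.
* **Training recipe** — equally weighted BCE + soft-Dice loss, RMSProp,
  batch size 1, sequential chronological fraction steps with teacher-forced
  priors, per-epoch patient shuffling, pre-training on simulated fractions
  followed by fine-tuning, and a reduce-on-plateau learning-rate schedule.
* **Fraction simulator** — smooth random displacement fields interpolated
  between −DVF and +DVF (scales −1, −0.5, 0, 0.5, 1) applied to image and
  contours, generating multi-fraction courses from a single volume.
* **Deformable phantoms** — multi-organ ellipsoid volumes with
  patient-specific organ intensities (so intensity alone cannot identify a
  structure — the CBCT ambiguity), letting every part of the pipeline run
  with no clinical data.
* **Runtime & baselines** — rigid prior alignment, sequential course
  prediction with revised / autonomous / registration-derived priors, the
  no-learning contour-prior baseline, and memory-free U-Net baselines
  (`unet_prior`, `unet_ds`).
* **Metrics** — Dice, Hausdorff / HD95 surface distances, per-structure and
  per-fraction summaries, pooled paired t-tests.

The neural-network machinery (3D im2col/GEMM convolutions, transposed
convolutions, pooling, a reverse-mode autodiff tape, RMSProp) is
implemented in the package itself with Rcpp/RcppArmadillo kernels — no
external deep-learning framework is required.

## Worked example

Simulate one patient, train briefly on their course, and evaluate:

```r
library(progseg)

# one 32^3 phantom with 3 organs, and a 5-fraction simulated course
ph  <- make_phantom(phantom_config(seed = 11))
dvf <- make_smooth_dvf(c(32, 32, 32), amplitude = 10, smoothness = 2,
                       seed = 12)
series <- simulate_fractions(ph$image, ph$contours, dvf)
series
#> <patient_series> sim: 32x32x32 grid, 3 structure(s), 5 fraction(s)

# a small LSTM-UNet (8 first-level features, 3 resolutions)
model <- seg_model(model_config("lstm_unet", out_channels = 3,
                                features = 8, levels = 3), seed = 5)
model
#> <progseg_model> variant lstm_unet, 3-channel input, 3 structure(s),
#>   features 8, levels 3, 376,315 parameters

# twenty sequential passes over the course (100 fraction steps)
cfg <- train_config(lr = 3e-3, seed = 1)
opt <- NULL
for (i in 1:20) {
  pass <- train_patient_pass(model, series, opt, cfg)
  opt <- pass$opt_state
}
round(pass$losses, 3)   # composite loss per fraction, last pass
#> [1] 0.074 0.069 0.044 0.057 0.076

# predict the whole course (memory carried fraction to fraction)
course <- run_course(model, series, register = FALSE)
atoms  <- evaluate_course(course, series)
summarize_metrics(atoms)$per_structure
#>   structure  mean_dsc     sd_dsc n
#> 1   organ_1 0.9311060 0.02455836 5
#> 2   organ_2 0.9385603 0.02822374 5
#> 3   organ_3 0.9310189 0.02806050 5
```

Each row is one organ's mean ± sd Dice across the 5 fractions of the
course: after ~100 training steps the memory-carrying model reproduces the
course's contours with Dice ≈ 0.93–0.94, while the rigid contour-prior
baseline on the same course (`contour_prior_course(series)`) scores ≈ 0.89
— the gain is what the prior-and-memory mechanism adds on anatomy that
deforms from fraction to fraction.

A shell front end wraps the same functions:

```sh
prog-seg simulate-phantom --shape 32 --n-structures 3 --seed 1 --out ph/
prog-seg simulate-fractions --in ph/ --out series/
prog-seg train --pretrain series/ --out ckpt.rds --features 8 --levels 3
prog-seg predict --ckpt ckpt.rds --series series/patient_sim --out pred/
prog-seg evaluate --pred pred/ --truth series/patient_sim --out report.csv
```

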