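---
title: "Progressive prior-guided auto-segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progressive prior-guided auto-segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In online adaptive radiotherapy (ART) a new cone-beam CT (CBCT), or a
synthetic CT derived from it, is acquired at every treatment fraction while
the patient waits on the couch, and the targets and organs-at-risk must be
re-contoured before the plan can be adapted. Direct auto-segmentation of
CBCT-quality images is unreliable — noise, artifacts and poor soft-tissue
contrast — and conventional models treat every fraction as an independent
image, rediscovering (and repeating) the same mistakes at each session even
though the same patient was contoured, and those contours clinician-approved,
only days earlier.

`progseg` treats the course as a *sequence*. Each fraction's input is a
3-channel stack — the previous fraction's (rigidly aligned) image, its
approved contours encoded as a label map, and the current image — and the
network carries an explicit per-patient memory from fraction to fraction, so
that by fraction k it has assimilated all k−1 previously approved
segmentations of this particular patient.

## The model

The backbone is a standard 3D U-Net: `levels` resolutions (default 5), two
(3×3×3 convolution → instance normalization → ReLU) blocks per level,
channel count doubling per level from `features` (default 32) first-level
channels, 2× max-pooling on the way down, kernel-2 stride-2 transposed
convolutions on the way up, and a final 1×1×1 convolution with per-structure
sigmoid outputs (multi-label, so abutting structures may overlap; masks are
binarized at 0.5 for evaluation).

The memory mechanism replaces each skip connection with a convolutional
LSTM unit. At level ℓ the encoder feature x(t) and the carried state
(h(t−1), c(t−1)) update through the standard four-gate equations,

    i = σ(W_xi * x + W_hi * h + b_i)     f = σ(W_xf * x + W_hf * h + b_f)
    o = σ(W_xo * x + W_ho * h + b_o)     g = tanh(W_xg * x + W_hg * h + b_g)
    c(t) = f ⊙ c(t−1) + i ⊙ g            h(t) = o ⊙ tanh(c(t))

where `*` is a resolution-preserving 3×3×3 convolution (no peephole
connections). The decoder consumes the cell state c(t) — not h(t) — through
the skip connection, with the bottom level's c(t) feeding the decoder trunk.
Passing c(t) rather than h(t) is unusual for LSTM architectures; it is
implemented literally here, and `model_config(decoder_skip = "h")` switches
to the conventional choice for comparison. Before a patient's first
fraction the memory is exactly zero (`init_memory()`), and it is cleared
again after the patient so that no information leaks between patients.

Two memory-free baselines share the identical topology with plain skip
connections: `unet_prior` takes the same 3-channel input, and `unet_ds`
sees only the current image (1 channel) — the conventional
direct-segmentation model.

### Initialization

Convolution weights use He-style scaling. Two deliberate deviations from
plain random initialization:

* forget-gate biases start at 1, so early in training the memory is
  retained rather than immediately forgotten — the standard LSTM trick;
* the output head's bias starts at −2, so initial foreground probabilities
  are ≈ 0.12 rather than 0.5. Structures occupy a few percent of the
  volume; starting near the background rate removes a long initial phase
  in which the Dice term only suppresses false positives.

## Training

The loss is the equally weighted composite of voxelwise binary
cross-entropy (probabilities clamped to [1e−7, 1−1e−7]) and soft Dice
(smoothing ε = 1e−6), averaged over structure channels. The optimizer is
RMSProp (smoothing 0.99, ε = 1e−8), batch size 1 — one fraction volume per
step — which is also why instance normalization is used instead of batch
normalization.

Training is sequential and chronological: memory zeroed, then for each
fraction of a patient the 3-channel input is assembled (fraction 1 uses the
planning image and contours as the prior; fraction k > 1 uses fraction
k−1's image with its *ground-truth* contours — teacher forcing, mirroring
the clinical reality that past fractions were clinician-approved), one
optimizer step is taken against the fraction's ground truth, and the
updated (h, c) is carried to the next fraction. By default the memory is
detached between fraction steps (truncated backpropagation through time:
one optimizer step per fraction, which matches the sequential recipe and
batch size 1); `train_config(tbptt = FALSE)` instead accumulates the loss
across the whole sequence and takes one step per patient, with gradients
flowing through the memory chain. Patient order is reshuffled every epoch
from a seed-derived permutation.

`fit()` runs two phases — pre-training (default 40 epochs) on a simulated
cohort, then fine-tuning (default 30 epochs) from the last pre-trained
checkpoint — with a reduce-on-plateau schedule: when the monitored loss has
not improved for `plateau_patience` (3) epochs the learning rate is
multiplied by `plateau_factor` (0.1), floored at `min_lr`. Defaults follow
the reference recipe: initial rate 1e−5, floor 1e−8. Two unstated details
were resolved as follows and are exposed in the configuration: the
scheduler monitors validation loss when a validation cohort is supplied
(else training loss), and fine-tuning restarts the optimizer and learning
rate rather than continuing the decayed schedule.

### Desk-scale schedules

The 1e−5 initial rate is calibrated to clinical-scale training
(≈ 18,000 fraction steps per epoch on the original cohort). The package's
own studies run a few hundred steps in total, where 1e−5 cannot move the
network measurably; they therefore use a staged schedule — a 2-epoch
warmup at 1e−3 (which stabilizes the early binding of prior-label values
to output channels), a long 3e−3 phase, then decay through 1e−3 to 3e−4 —
which plays the role the plateau scheduler plays over the long schedule.
The study sizes are: overfit study — one patient, 32³ voxels, 3 fractions,
LSTM-UNet with 8 features / 3 levels, ≤ 200 fraction steps; cohort study —
8 patients (6 train / 2 held out), 32³, 5 fractions, 4 features / 3
levels, 26 epochs. Because the binding of prior-label values to output
channels can land in a poor optimum at this data scale, the cohort study
selects the LSTM-UNet checkpoint by Dice on two *validation* patients
simulated independently of the held-out pair (mirroring the clinical
protocol's train/validation/test split), and permits one random restart
when no checkpoint beats the registration baseline on validation;
selection never sees the held-out patients. Even so, the cohort ordering
(no-prior U-Net below the rigid contour-prior baseline, LSTM-UNet at or
above it) is a stochastic property: at this cohort size the learned
model's margin over the copy baseline varies across random cohorts, and
occasional draws whose held-out patients have weakly separated organ
intensities can fall below it. These sizes keep each study in the
minutes range on a single CPU while leaving the full-scale defaults
(32 features, 5 levels, 40 + 30 epochs) available for real use.

## Simulated data

### Phantoms

`make_phantom()` places `n_structures` ellipsoidal organs (radii ≈ 10–18 %
of the grid, at least 2 voxels of separation, shrinking adaptively in
crowded volumes) over a 0.1-intensity background, with additive Gaussian
noise (sd 0.03) and intensities already normalized to [0, 1] — CBCT
preprocessing (HU clipping, normalization) is considered upstream of the
tool. Organ intensities are drawn *independently per patient* (0.35–0.95,
pairwise separated by ≥ 0.05). This is the phantom's key emulation of CBCT
ambiguity: absolute intensity does not identify a structure across
patients, so a model without prior contours cannot learn a fixed
intensity→organ mapping — exactly the failure mode that makes
direct segmentation weak on real CBCT.

### Fractions

Anatomical change over the course is emulated by a smooth random
displacement field (per-component Gaussian white noise, separably smoothed,
rescaled to a maximum displacement `dvf_amplitude`). Following the
simulation recipe, the field is interpolated between −DVF and +DVF at
scales (−1, −0.5, 0, 0.5, 1), each scaled field applied to both the base
image (trilinear) and its contours (nearest-neighbour), yielding 5
simulated fractions per patient; the scale-0 fraction is kept and is
bit-identical to the base. Negation is a literal sign flip of the field,
not a true inverse deformation — that discrepancy is part of the method as
specified. Displacements are stored in voxel units (all in-repo grids share
spacing) with backward (pull) warping and edge-clamped sampling.

The deformation defaults (`dvf_amplitude = 10` voxels,
`dvf_smoothness = 2`) are calibrated against the clinical regime: with
them, rigidly-aligned prior contours on consecutive simulated fractions
score a mean Dice in the mid-0.80s on held-out phantoms, matching what
registration-based contour propagation achieves on real serial imaging.
Very smooth fields are nearly rigid locally and are absorbed by the rigid
pre-alignment, which is why the smoothness scale matters as much as the
amplitude.

### What the phantom does not emulate

No CT physics (scatter, beam hardening, ring artifacts), no realistic
anatomy or inter-structure topology, no couch-shift rigid offsets, no
observer variability in the "approved" contours, and organ appearance is
piecewise-constant rather than textured. Passing the package's studies
therefore demonstrates that the architecture, memory mechanism, losses and
training loop function end-to-end and that prior-guided memory helps when
intensity alone is ambiguous — it does not certify clinical performance.

## Inference runtime

`run_course()` reproduces the online workflow: memory zeroed; fraction 1
uses the planning image and contours as prior; later fractions use the
previous fraction's image and contours, rigidly aligned to the current
image before assembly. Three prior modes reflect three operating points:

* `revised` (default): ground-truth prior contours, the clinical situation
  where every past fraction was approved by a clinician;
* `auto`: the model's own previous predictions — degradation studies;
* `dir`: contours deformed onto the current anatomy by an external
  deformable registration; the matching prior image is then the current
  image itself, so channels 1 and 3 coincide. Deformable registration
  itself is out of scope: at phantom scale the simulator's known field
  acts as a registration oracle (the default supplies each fraction's own
  ground truth; noise-corrupted sets model imperfect registration).

Rigid alignment is a translation-only, coarse-to-fine exhaustive search
minimizing mean squared intensity difference (phantom series contain no
rotational offsets; the transform container supports rotations for data
that do). The `contour_prior` baseline — previous contours, rigidly
aligned, used directly — is the no-learning reference point.

## Evaluation

Dice is 2|A∩B|/(|A|+|B|); two empty masks score 1.0 (absence agreed) and
exactly one empty mask 0.0 — a convention the degenerate case requires and
the reference formulation leaves open. Hausdorff distances are computed on
boundary voxels (foreground with a 6-neighbour background, or on the volume
edge), in mm via the voxel spacing, without sub-voxel surface meshing:
deterministic and adequate at phantom resolution. HD95 is the maximum of
the two directed 95th percentiles. The pooled paired t-test concatenates
per-structure score arrays before testing — pooling non-independent
observations, as in the reference analysis; per-structure tests can be run
from the same atoms with `paired_t_test()` directly.

## Known limitations

* The dense LSTM convolutions at every level make the full 5-level,
  32-feature model large (~10⁸ parameters in double precision); desk-scale
  studies use reduced configurations.
* Truncated backpropagation means long-range credit assignment across many
  fractions relies on the carried state, not on gradients; the
  `tbptt = FALSE` path exists but is costlier.
* The rigid registration is translation-only by design; rotational
  misalignment must be handled upstream or via a supplied transform.
* Phantom realism, as listed above: conclusions transfer to clinical data
  only at the level of mechanism, not of absolute accuracy.
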