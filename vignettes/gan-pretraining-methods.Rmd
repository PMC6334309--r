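---
title: "GAN-augmented pretraining for nodule classification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GAN-augmented pretraining for nodule classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleGAN)
```

## The problem and the method

Benign and malignant pulmonary nodules are hard to distinguish on CT, and
the biopsy that settles the question is invasive. Supervised classifiers
help, but clinical cohorts with pathological ground truth are small —
dozens of cases, not thousands — and deep convolutional networks trained
from scratch on so few images overfit badly.

The approach implemented here attacks the data-scarcity problem in two
stages:

1. **Synthesize.** Train one Wasserstein GAN per class on augmented 2-d
   sections of the available nodules, then sample as many synthetic nodule
   images as desired.
2. **Stage the training.** Pretrain a convolutional classifier to separate
   generated-benign from generated-malignant images, replace its fully
   connected layers with fresh random weights, and fine-tune the whole
   network on the real nodule sections.

The intuition is that the GAN images, though imperfect, teach the
convolutional stack generic nodule morphology (blob-like cores, margins,
spiculation, pleural contact), so fine-tuning starts from features adapted
to the domain rather than from noise.

Because clinical CT datasets of this kind are private, the package ships a
synthetic phantom generator that reproduces the *statistical structure* of
such a cohort, so that every stage — and the benefit of pretraining
itself — is testable end to end on any machine.

## The data model

A `CTVolume` is a 3-d HU-intensity grid with voxel spacing and origin; a
`NoduleAnnotation` gives a nodule's center (mm), maximum diameter (mm),
class label, and an *isolated* flag (pleura-attached nodules are excluded
from GAN training, where mixed morphology destabilizes the generator). A
`VOICube` is the isotropically resampled cube around one nodule, with
physical side twice the annotated maximum diameter. A `PatchImage` is one
2-d section with full provenance (case, orientation, symmetry op), which
the evaluation layer uses to guarantee case-level splits.

## The phantom generator

`generateCase()` draws, in a fixed seeded order: the spicule count
(malignant only), the maximum diameter, the ellipsoid axis ratios, the
pleural-attachment flag, the center position, the spicule geometry, and
finally the voxel noise. Morphology follows the radiological caricature:

* **Benign**: near-spherical soft ellipsoid (axis ratios 0.92–1.0), core at
  +40 HU over a −800 HU lung background, with a Gaussian edge profile of SD
  5% of the diameter. Inside the core the intensity equals the nodule
  intensity exactly; beyond three edge-SDs the field is exactly background
  (the profile is truncated), which the noise-free tests exploit.
* **Malignant**: a more eccentric ellipsoid (ratios 0.72–0.95) carrying
  4–10 radial spicules — line segments from the surface outward, length a
  fraction (default 0.6) of the radius, with linearly decaying intensity
  and a tapering Gaussian cross-section of thickness `max(1.2 mm, 0.1 d)`.
* **Pleural attachment**: with configurable probability (default 0.3
  malignant, 0.37 benign) the nodule is placed near the chest-wall slab at
  the x-max face and joined to it by a soft bridge; such cases are flagged
  non-isolated.

All intensities are clamped into [−1024, +400] HU. Per-case seeds derive
from the master seed by a named 31-bit polynomial hash (`deriveSeed`), so
cohorts are bit-reproducible on any platform regardless of generation
order.

**What the phantom does and does not emulate.** It reproduces the
intensity scale, the benign/malignant morphology contrast, class
imbalance, pleural attachment, per-case size variation, and additive
noise. It does *not* contain airways, vessels, reconstruction texture, or
partial-volume effects, and its class contrast is cleaner than clinical
reality. Passing tests therefore demonstrate that the pipeline's
machinery — augmentation arithmetic, GAN training dynamics, the transfer
protocol, leakage-free evaluation — behaves correctly, not that the
reported accuracies transfer to hospital data.

A deliberately crude independent check, `shellVariance()`, measures
intensity variance in the 1.2–1.8-radius spherical shell (excluding the
solid angle toward the chest wall, where attachment would swamp the
statistic for both classes). Leave-one-out nearest-neighbor on this one
number separates the default phantom classes with >80% accuracy, which
guarantees the downstream learning problem is winnable before any network
enters the picture.

## VOI extraction and augmentation

`extractVOI()` resamples once, trilinearly, to an isotropic grid (default
1 mm) — oblique reslicing of an anisotropic grid would distort angles, so
isotropy is established first. The cube side is `round(2 d / res)` forced
odd, so the annotated center is exactly the central lattice point (this
makes the 0°-section identity test exact). Samples outside the source
volume take air density (−1024 HU) rather than edge-clamping, since real
nodules abut the pleura.

`obliqueSlice()` tilts the axial plane about one of the two in-plane axes
by −40°…+40° and samples through the cube center. `dihedralExpand()`
applies exact lattice rotations/flips (no interpolation). The default
grid — 16 non-zero angles × 2 axes × 8 dihedral ops — yields exactly 256
sections per nodule. A single-axis variant with 17 angles including 0°
(136 per nodule) is available via `augmentConfig(tiltAxes = "x",
includeAxial = TRUE)`; the two-axis reconstruction is the package default
because it reproduces the 256× augmentation factor while preserving the
stated angle range and step. Which convention produced the original
augmented counts cannot be settled from the available description; the
choice is exposed in configuration rather than hidden.

## The Wasserstein GAN

The generator maps a 100-d latent, uniform on [−1, 1], through a dense
projection to 4×4 feature maps and four fractionally strided 5×5
convolutions (stride 2, output padding 1), doubling resolution each layer:
4→8→16→32→64, with batch normalization everywhere except the tanh output
layer. The critic mirrors this with four strided 5×5 convolutions (batch
normalization on each, switchable off) and a final linear map to a single
unbounded score. Channel widths are 512/256/128/64 at full scale and
64/32/16/8 in the `tiny` preset.

Training follows the weight-clipped Wasserstein recipe: `nCritic` critic
updates minimizing `mean f(G(z)) − mean f(x)` with every critic parameter
clipped into [−c, c] (default c = 0.01) after each update, then one
generator update maximizing `mean f(G(z))`, all under RMSprop. The
clipping constant and `nCritic = 5` follow the original weight-clipping
algorithm, since only the optimizer, rate and epochs are pinned by the
protocol (learning rate 0.00005, 1000 epochs at full scale). GANs are
always trained per class; `trainWGAN()` refuses mixed-label inputs.

Numerical notes: the Wasserstein estimate of two identical batches through
the same critic is exactly 0; the clipping invariant can be asserted
in-loop via `debugCheckClip`; with batch normalization in the critic and
generator, inference (`generateImages`) uses stored running statistics and
is a pure function of (weights, latents).

**Tiny-scale learning rate.** At 1/8 channel widths and under a hundred
RMSprop steps, the full-scale rate (5e-5) barely moves the generator, so
every tiny-scale run in this package (tests, the `tiny` preset, the
benefit experiment) uses 5e-4. The `paper` preset echoes 5e-5 unchanged.

## The classifier and the staged protocol

The full-scale network follows the classical five-conv/three-pool/three-FC
design: input resized to 256×256 and center-cropped to 227×227, conv1 with
96 kernels of 11×11 at stride 4 (feature map 55×55×96), 3×3/stride-2 max
pooling (27×27×96 after pool1), conv2–conv5 with 256/384/384/256 channels,
and fully connected layers 4096/4096/2 with dropout 0.5. The stated input
size (256) and the stated conv1 output (55) are only mutually consistent
under the 227 center-crop convention, which this package adopts
unconditionally; the shape contract is asserted at construction and traced
by a real forward pass in the tests.

`pretrainClassifier()` trains the whole network from random init to
separate generated-benign from generated-malignant images (SGD with
momentum 0.9; the pretraining schedule is not pinned by the protocol and
defaults are package choices). `finetuneClassifier()` then rebuilds the
three FC layers from fresh Gaussian weights (SD 0.01 at full scale — the
Caffe convention), copies the convolutional stack from the pretrained
model, and trains all layers by SGD (full-scale default: 30 epochs at
0.0001). With `epochs = 0` it returns the replaced-FC model unchanged,
which the replacement-contract test uses. Scratch training is the same
call starting from `buildClassifier()` — i.e. the protocol degenerates to
ordinary training when pretraining is skipped.

The `tiny` preset is a 32×32 analogue with the same
conv/pool/FC organization (8/16/16 channels, FC 64/32/2, dropout 0.5) used
in all CPU-scale experiments.

## Evaluation

Cases — not images — are the cross-validation unit: reported per-class
accuracies in this field are over cases, and augmented views of one nodule
are near-duplicates, so image-level splits would leak. `makeFolds()`
stratifies by class (27/33 at k = 3 gives 9/11 per fold); every fold run
audits that no case contributes patches to both sides. Per-fold GANs are
trained only on that fold's *training* cases flagged isolated. A case's
prediction is the mean of its view probabilities (median and axial-only
are exposed); the decision threshold is 0.5 with ties to malignant; ROC
curves sweep every distinct aggregated probability and the AUC is
trapezoidal, with tied scores treated as one threshold step.

## The benefit experiment and its study conditions

`pretrainingBenefit()` is the package's headline property experiment: per
seed, a fresh 20-case phantom cohort (10/10), one stratified third held
out, and the two arms — WGAN-pretrained versus scratch — trained with
identical splits, fine-tuning schedule and seeds, differing only in the
initialization of the convolutional stack. CPU-scale conditions, chosen
once: 32×32 working images, a reduced view grid (±40° about both axes, 4
rotations — 16 views per nodule), tiny widths, WGAN at lr 5e-4 for 15
epochs with nCritic = 2, pretraining 8 epochs at 0.02, fine-tuning 40
epochs at 0.02 (batch 16 throughout). Held-out sets of ~7 cases make
single-seed contrasts noisy by construction — one flipped case moves a
per-seed difference by 12–14 accuracy points — so the quantity of interest
is the *paired mean* over seeds, mirroring the structure (not the
magnitude) of the full-scale finding that GAN pretraining raises per-class
accuracy over training from scratch. Even that mean carries a standard
error of several points at 5 seeds: replicate streams can land on either
side of zero, and a definitive estimate would need more folds and seeds
than a desk-scale run affords. Both arms routinely fit the training cases
perfectly; everything at stake is generalization from ~13 cases, which is
exactly the small-sample regime the method targets.

## Degenerate inputs and edge behavior

Empty cohorts are valid (empty list); zero-epoch WGAN training returns the
initial weights and an empty trace; aggregation of an empty probability
vector, one-class metric/ROC inputs, mixed-label GAN sets, non-square
patches, sub-batch-size training sets, out-of-range tilt angles, and
volumes smaller than twice the maximum configured diameter all raise
informative errors. NIfTI volumes with oblique (non-axis-aligned) affines
are rejected outright rather than silently misoriented; the raw fixture
format stores float64 voxels and round-trips bit-exactly.

## Known limitations

* The phantom's class contrast is idealized; absolute accuracies obtained
  on it say nothing quantitative about clinical CT.
* Weight clipping is the original, simplest Lipschitz device; gradient
  penalty variants are deliberately out of scope.
* The training engine is plain CPU code (BLAS matrix products behind
  im2col); it is sized for the tiny preset and for single forward passes
  of the full-scale network, not for full-scale training.
* DICOM series assembly is not implemented; real deployments would add it
  in front of `readVolume()`.

## Problem sizes used by the shipped experiments

Tests and the acceptance script run: gradient checks on 8×8 tensors;
phantom cohorts of up to 60 cases at 48³–64³ voxels; augmentation counts
on 5 and 11 nodules; one 227×227 forward pass of the full-scale
classifier; a 50-generator-step tiny WGAN run (batch 16); a 7-epoch toy
WGAN recovery run on 500 constant images; the 5-seed benefit experiment
described above; and the `tiny` end-to-end pipeline (20 cases, 3 folds,
both strategies).
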