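---
title: "Classifying pulmonary nodules in PET volumes with 3D CNNs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pulmonary nodules in PET volumes with 3D CNNs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Indeterminate solid pulmonary nodules (8--30 mm) imaged with 2-[18F]FDG
PET must be classified as benign or malignant. The conventional
quantitative marker is SUVmax, the maximum standardised uptake value
inside the lesion. `petnodcnn` implements an alternative: a 3D
convolutional neural network that maps a nodule-centred PET subvolume
X (a 40 x 40 x 40 single-channel tensor at 1.5 mm isotropic spacing) to
a malignancy probability, trained end-to-end with stratified 4-fold
cross-validation, ensembled across folds, and compared against SUVmax
with paired nonparametric ROC tests.

Because clinical PET cohorts cannot be redistributed, the package ships a
first-class phantom simulator that reproduces the *statistical structure*
such an analysis assumes, so every stage is testable without any
download.

## The phantom cohort

`phantom_spec()` defines the cohort: 113 subjects, 45.1% malignant
prevalence (51 malignant / 62 benign, allocated exactly), nodule
diameters log-normal with median 13 mm and IQR 5 mm truncated to the
(8, 30] mm eligibility window, and a uniform background of physiological
uptake (1.0 SUV) plus peripheral hot spots emulating organs with
physiological tracer uptake.

Each nodule is an ellipsoid whose per-axis radii are jittered +/-20%
around diameter/2; its plateau uptake is `background x contrast`, with
the contrast drawn log-normally around a class median (benign 1.5,
malignant 4.0, log-sd 0.35, truncated below at 1). The volume is blurred
with a Gaussian point-spread function of 6 mm FWHM -- a typical PET
reconstruction resolution -- which produces the partial-volume contrast
loss that makes small nodules dimmer than their nominal contrast.
Additive Gaussian noise (sd 0.1 SUV) is truncated at zero to respect SUV
non-negativity; the additive-Gaussian choice mirrors the noise model used
for augmentation rather than the Poisson statistics of raw counts. Raw
phantoms are generated at anisotropic scanner-like spacing (2, 2, 3 mm)
so that isotropic resampling is a real, exercised step.

The contrast defaults are artifact choices, not estimates of any clinical
population: they make the task learnable but imperfect (the benign and
malignant contrast distributions overlap). Consequently the phantom
cohort is *cleaner* than clinical data -- no respiratory motion, no CT
anatomy, no scanner heterogeneity beyond voxel spacing -- and
cross-validated AUCs on phantoms (typically 0.9--1.0) sit above what the
same architecture attains on real nodules. Passing the pipeline's tests
demonstrates that the machinery recovers a known signal, not that the
model reaches clinical performance.

## Preprocessing

Volumes are resampled to 1.5 mm isotropic voxels by trilinear
interpolation in physical coordinates (voxel-centre convention, 0-based
indices, axis 3 axial), then cropped to a 60 mm cube -- twice the maximum
eligible nodule diameter -- centred on the voxel nearest the annotated
nodule centre, giving the 40^3 input. With an even side length the centre
voxel sits at 0-based index 20 on each axis; out-of-volume regions are
zero-filled.

Min--max normalisation to [0, 1] is *fold-specific*: the minimum and
maximum are global scalars over every voxel of the fold's original
training tensors, and the same statistics normalise that fold's
validation and test inputs. Per-volume scaling would destroy
inter-subject SUV contrast, which is the main discriminative signal.
Out-of-range validation/test values are not clipped by default
(information-preserving); a `clip` flag exists for sensitivity analysis.
Statistics are fitted before augmentation and then applied to the
augmented copies, the natural order for offline augmentation whose noise
scales are defined on the normalised intensity scale.

## Offline augmentation

Augmentation is class-balanced and offline, with each augmented example
carrying exactly one transform:

* translations: independent integer shifts per axis, uniform in
  [-10, 10] voxels (15 mm at 1.5 mm spacing, small enough that a centred
  nodule never leaves the tensor, so the label is preserved); vacated
  voxels are zero-filled;
* rotations: uniform in [-45, 45] degrees about one axis through the
  tensor centre (the composite translate--rotate--translate-back
  transform), with in-plane bilinear resampling, evenly apportioned over
  the three axes; angles below 1 degree are rejected to avoid
  near-duplicates;
* Gaussian noise at sd 0.1, 0.3 and 0.5 on the normalised scale.

The per-class factors are 20/21/20 (minority = malignant) and 16/15/16
(majority) for translations/rotations/noise, so a 41/49 cohort expands to
41 x 62 + 49 x 48 = 4894 images with a post-augmentation minority
fraction of 0.52. Per-subject draws are sub-seeded from the plan seed and
the subject id, so datasets are reproducible subject-by-subject.

## Architectures

Three 3D CNN families are built declaratively (`build_stacked3d()`,
`build_vgg_like()`, `build_inception_like()`); all take the 40^3 input,
use LeakyReLU (alpha = 0.3) everywhere except the single sigmoid output
unit, He initialisation (N(0, 2/fan_in)), and an L2 penalty on kernel
weights.

* **Stacked 3D CNN** (the final-model family): four valid 3^3
  convolutions (8, 16, 32, 64 filters) alternating with 2^3/stride-2
  max-pools, then dense 32-16-1. Spatial chain:
  40 -> 38 -> 19 -> 17 -> 8 -> 6 -> 3 -> 1; flatten width 64.
* **VGG-like**: stacked valid 3^3 convolutions with overlapping
  same-padded 3^3/stride-2 max-pools; chain
  38 -> 19 -> 17 -> 15 -> 8 -> 6 -> 4 -> 2 -> 1, flatten width 32.
  Factorising 5^3/7^3 kernels into stacks of 3^3 preserves the receptive
  field while cutting parameters far more strongly in 3D than in 2D
  (79,873 versus 191,921 for the unfactorised equivalent,
  `count_parameters_unfactorised()`).
* **Inception-v2-like**: a 3^3 stem and pool, four standard inception
  modules (1^3 branch, 1^3->3^3, 1^3->3^3->3^3, pooled 1^3-projected
  branch, concatenated) and two stride-2 reduction modules, global
  average pooling, one output unit. The branch widths -- (8,8,8,8) before
  the first reduction, (16,16,16,16) after, reduction widths (16, 32) --
  are genuinely open design parameters; they are declared as builder
  arguments so alternates are one-line changes.

Two details the architecture description leaves open were decided as
follows: the dense hidden layers of the stacked network use LeakyReLU
like the convolutional layers (a uniform activation policy), and the L2
penalty applies to kernels only, the common framework convention; both
are explicit code paths rather than hidden constants.

## Training, cross-validation, ensembling

The cohort is split into five stratified partitions by largest-remainder
allocation (per-class counts within one of proportional; remainders dealt
to the smallest partitions). P1--P4 feed 4-fold cross-validation; P5 is
held out and touched exactly once, at the end. Training minimises binary
cross-entropy plus the L2 penalty with Adam (beta1 0.9, beta2 0.999,
epsilon 1e-7 -- the framework defaults the study tuned only the learning
rate against). The training set reshuffles every epoch; "full-batch"
means the actual training-set size. Early stopping monitors the
validation loss with patience 10 up to 100 epochs and restores the
best-epoch parameters. Gradients of large batches are accumulated over
micro-chunks of 16 samples, which is numerically identical to a single
large batch but memory-bounded. Training is single-CPU deterministic
given a seed; `repeat_cv()` retains the study's 10-iteration averaging
protocol for parity, with iteration 1 reproducing a plain
`cross_validate()` call.

The final classifier is the ensemble of the four fold models, averaging
probabilities with weights proportional to each fold's training-partition
size; each fold model normalises inputs with its own fold statistics.

## ROC analysis and thresholds

All ROC machinery is nonparametric and uses the classify-at->= convention
throughout. The AUC is the trapezoidal integral over operating points at
every distinct score, which equals the Mann--Whitney pair-counting
statistic with ties counted one half (property-tested). DeLong structural
components give the AUC variance, normal-approximation confidence
intervals truncated to [0, 1], and the paired AUC test.

Two decision-threshold rules are selected on each fold's validation
partition and averaged across folds: the Youden rule (maximise
sensitivity + specificity - 1, ties toward the lower threshold, i.e.
higher sensitivity) and the sensitivity-constrained rule (specificity
maximised subject to sensitivity >= 95%), the latter encoding the
asymmetric cost of missing a malignant nodule.

The CNN-versus-SUVmax comparison dispatches on curve crossing: the paired
DeLong test when one ROC curve is uniformly dominant on the union FPR
grid, the Venkatraman--Begg shape test when the curves cross. The
Venkatraman--Begg statistic E sums absolute differences in classification
errors over all within-modality rank cutpoints; its null distribution
exchanges the two modalities within subject with probability one half,
2000 permutations by default, with ties broken by uniform jitter smaller
than a quarter of the minimal score gap, redrawn and re-ranked per
permutation (the continuous-data variant of the test; E is therefore an
integer on tie-free data and matches the reference implementation in
pROC exactly, as the test suite verifies). The p-value is the plain tail
fraction `mean(E_perm >= E_obs)`.

## Explanations

`gradcam3d()` implements 3D Grad-CAM on the pre-sigmoid logit (the
standard choice; the probability's extra sigmoid factor only rescales
the map). Channel weights are spatial averages of the logit gradient at a
convolutional layer; the rectified weighted feature-map sum is
trilinearly upsampled to the input grid and max-normalised, with
identically zero maps passed through unchanged. For the stacked network
the last convolution has 1^3 spatial extent, whose upsampled map would be
uniform and uninformative, so the default explanation layer is the
deepest convolution retaining at least 2 voxels of spatial extent (its
penultimate convolution, 6^3). Galleries reformat volumes into ten thick
axial slices (means of four consecutive slices) and fuse PET grayscale
with a red-dominant heat ramp whose opacity scales with the local
Grad-CAM score.

## Numerical choices and degenerate inputs

* Resampling clamps coordinates at the grid edge; rotation zero-fills
  out-of-grid samples (background is zero after normalisation).
* `fit_minmax()` refuses degenerate (constant) training sets; perfect
  separation yields a zero-width truncated DeLong interval, flagged.
* A zero-variance paired AUC difference returns p = 1 with a warning
  rather than a spurious z-score.
* Sub-seeding uses a multiplicative congruential mix over tag characters
  modulo 2^31 - 1, so every derived seed is a valid R seed and all
  arithmetic stays exact in doubles.

## Problem sizes used by the tests and the reproduction script

The test suite and `scripts/acceptance.R` run the full 113-subject
phantom cohort with the stacked architecture at learning rate 0.001,
mini-batches of 8 and up to 15 epochs (patience 10) -- enough updates for
the phantom task to saturate, as the training-history tests show, and a
deliberate reduction from the 100-epoch ceiling used for real data.
Augmentation accounting is exercised on reduced 8^3 tensors (the counts
are shape-independent); statistical calibration uses 300 null replicates
of 200 permutations at n = 60. Module tests use miniature architectures
on 6^3--16^3 inputs with finite-difference gradient checks.

## Known limitations

* The phantom cohort omits CT anatomy, attenuation artefacts,
  respiratory motion and scanner-specific reconstruction; transfers of
  performance numbers to clinical data are not meaningful.
* Online (in-loop) augmentation, elastic deformations and mixup are out
  of scope, as are smoothed ROC fits, partial AUC, and multi-class
  problems.
* The 2D transfer-learning baseline of the original experiment requires
  external pretrained weights and is deliberately excluded.
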