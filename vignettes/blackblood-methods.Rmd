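---
title: "Vessel-suppressed black-blood synthesis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel-suppressed black-blood synthesis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bbsynth)
```

## The problem

Contrast-enhanced 3D gradient-echo (CE 3D-GRE) brain MRI shows both
metastatic lesions and blood vessels as bright structures, so tiny
metastases near the cortex are easily confused with cortical vessels.
Black-blood (BB) sequences suppress flowing-blood signal — vessels go
dark, enhancing metastases stay bright — but cost an extra scan of
several minutes and themselves suffer imperfect suppression. `bbsynth`
implements a pipeline that learns to produce a vessel-suppressed volume
directly from the GRE input:

1. **Auto-labelling** builds a training target (a *synthetic BB* volume)
   from a registered GRE/BB pair by finding vessel voxels on the GRE
   image and replacing them with the co-located BB values, leaving all
   other tissue — in particular metastases — untouched.
2. A **3D residual CNN** is trained on co-located 31×31×31 patch pairs
   (GRE input, synthetic BB label) and then applied to new GRE volumes,
   yielding *deep-learned BB* volumes without a BB acquisition.
3. **Evaluation** quantifies vessel suppression with the ROI-based ratio
   `R_s`, scores per-lesion/per-patient detection against ground truth,
   and measures rater agreement with weighted kappa.

Because real paired patient data cannot ship with a package, a **3D
phantom generator** reproduces the geometry of the task — three vessel
caliber classes, blob metastases, two tissue contrasts, noise, blur and
imperfect BB suppression — with exact voxel-level ground truth. Every
stage of the pipeline is exercised and tested against that truth.

## The auto-labelling model

The chain is: intensity normalization (divide by the volume maximum so
the range is [0, 1]), brain extraction, then two vessel-extraction
passes.

**Pass 1 — clustering and growing.** Fuzzy c-means (FCM) clusters brain
voxel intensities into `n_clusters` (default 3) classes. FCM minimizes
$J = \sum_i \sum_k u_{ik}^m (x_i - c_k)^2$ subject to
$\sum_k u_{ik} = 1$, with fuzziness $m = 2$; memberships and centroids
are updated alternately, which makes $J$ non-increasing. Centroids are
initialized at fixed intensity quantiles and kept sorted, so the run is
deterministic and the *brightest* class — white matter plus vessels on
GRE — is always the candidate class. Region growing then separates
vessels from bright parenchyma: seeds are candidate voxels in the top
`1 - seed_percentile` fraction (default top 0.5%) of candidate
intensities, and the region expands through 26-connected candidate
voxels whose intensity stays within `grow_tol` (default 0.1) of the
seed-region mean. Vessels are connected, near-maximal structures on
normalized GRE, so growth covers them while isolated blobs (metastases)
are excluded twice over: they are darker than the vessel seed mean and
not connected to the seeded trunks.

Seeds must also exceed an absolute floor (`seed_floor`, default 0.8 in
normalized units). A purely rank-based seed rule always finds "seeds"
even in a volume with no bright structure at all (the top percentile of
white-matter noise), and would then grow a spurious mask through
parenchyma. After max-normalization enhancing vessels sit near the top
of the unit range, so the floor is a weak assumption that buys an
important property: on a vessel-free volume the pass returns an empty
mask and the pipeline is an exact identity.

**Replacement and blending.** Mask voxels take the co-located BB value
exactly. Because a hard cut-over creates a step in intensity at the mask
edge, a one-voxel dilated ring (26-neighbourhood) is blended as
`0.5·BB + 0.5·GRE` (`blend_weight_bb`, `dilation_radius_vox`
configurable).

**Pass 2 — difference-image thresholding.** Vessels missed by pass 1
(typically thin cortical branches whose connection to a trunk is not
captured) remain bright in the intermediate synthetic BB volume.
Thresholding that volume directly would also catch bright white matter;
subtracting the BB image first cancels everything the two volumes agree
on, leaving unreplaced vessels as the dominant positive residue. Voxels
with difference above `residual_threshold` form the pass-2 mask, which
is filled the same way (the ring now blends the intermediate volume with
BB).

`residual_threshold` defaults to 0.2 in normalized units. The value
separates three populations of the difference image: unreplaced vessels
sit near `GRE_vessel − BB_background` (≈ 0.9 on default phantoms),
white matter near the GRE−BB tissue-contrast gap (≈ 0.07), and lesions
near the inter-modality lesion gap (≈ 0.03) — but blur on the BB volume
drags the edges of small lesions down, inflating their difference values
toward 0.1–0.15. With additive noise of sd 0.02 per volume the
difference noise is ≈ 0.028, so 0.2 leaves > 3 sd of margin above the
lesion-edge population while keeping > 20 sd of margin below vessels. A
threshold sweep utility is unnecessary precisely because the populations
are this well separated; on real data the threshold is exposed in
`autolabel_params()`.

Degenerate inputs are handled explicitly: constant-intensity regions
make FCM fail with an error; an empty candidate class or no voxel above
the seed threshold returns an empty mask with a warning (and the
pipeline degenerates to the identity); non-positive thresholds are
rejected.

## The network

The image-to-image model is a plain stack of 3×3×3 convolutions with
zero padding of one voxel on every face (shapes are preserved at every
layer, including the through-plane axis), batch normalization and ReLU
after every layer except the last, a single feature map in the final
layer, and an elementwise addition of the network input to the final
convolution output. The residual formulation means the identity map is
available at initialization — with a zeroed final layer the network *is*
the identity, exactly — so training only has to learn the correction
(suppress vessels, mildly denoise) rather than the whole intensity map.

The full-scale configuration (25 layers, width 64, batch-normalized) is
constructible and unit-tested; training it is a multi-day GPU-scale job
and is not run here. The desk-scale configuration used throughout the
phantom studies is 5 layers of width 16 (receptive field 11³, enough to
tell a tube from a blob at phantom vessel calibers) *without* batch
normalization: at a few hundred optimizer steps, per-batch whitening
discards the absolute intensity scale that separates enhancing lesions
(≈ 0.85) from the brighter blood pool (≈ 0.95), so a batch-normalized
desk run see-saws between suppressing everything bright and sparing
lesions as the batch composition shifts. Dropping the normalization
makes the desk-scale loss decline monotonically and the
lesion-preservation behaviour stable. (At full scale, with five orders
of magnitude more optimizer steps, batch-normalized networks recover
absolute-intensity information through their bias and scale terms; the
batch-norm code paths — training statistics, backward pass, running
statistics at inference — remain fully exercised by the unit tests.)

Training minimizes voxelwise MSE with Adam (conventional secondary
constants β₁ = 0.9, β₂ = 0.999), gradients clipped to global L2 norm
`grad_clip = 1` per step, and a step learning-rate schedule that divides
the rate by 10 every 10 epochs (so a 1e-5 run is at 1e-6 from epoch 10).
Fine-tuning repeats training with the initial rate divided by 10 and a
60-epoch cap. Early stopping monitors validation MSE and stops once
`patience` consecutive epochs fail to improve the best value by a
relative `min_delta`; batch-norm inference always uses accumulated
running statistics (momentum 0.1).

The full-scale schedule (initial rate 1e-5, 30 epochs) is tied to a
training corpus of tens of volumes and hundreds of thousands of
optimizer steps; at desk scale — hundreds of steps — that rate cannot
move the weights measurably. `desk_train_config()` therefore uses a
conventional Adam rate of 1e-3 (2e-3 in the worked end-to-end study),
batch 5, and a 10-epoch cap with patience 3, while keeping the loss,
clipping rule, schedule shape, patch size (31³) and co-located sampling
identical to the full-scale configuration.

Patch sampling draws seeded-uniform origins valid for both volumes of a
registered pair; when phantom truth is available, at least
`fg_fraction` (default 0.5) of patches are required to contain vessel or
lesion voxels so that the informative minority of the volume is not
swamped by background, and half of that foreground quota must contain
lesion voxels. Lesions occupy roughly one percent of the brain, yet they
are the voxels the loss must *preserve* while everything bright around
them is suppressed; without the quota, a short desk-scale run sees so
few lesion examples that it learns "bright implies suppress" before it
ever learns the exception. Whole-volume inference tiles large volumes with
margins equal to the receptive-field radius; tiles are clipped at the
volume faces so the engine's per-layer zero padding coincides with a
whole-volume pass, making tiled and direct inference agree voxel for
voxel.

The convolution engine itself is a compact single-precision
im2col + GEMM implementation (with analytic batch-norm and convolution
gradients) written for this package; it is deterministic for fixed
seeds, which the reproducibility tests rely on.

## The phantom

The phantom is an ellipsoidal brain (semi-axes 40% of the grid) with a
~4 mm grey-matter shell and white-matter core, on a 96³ grid at 1 mm
isotropic spacing by default — small enough for CPU training, large
enough for 31³ patches and for the nine-ROI evaluation scheme.

* **Vessels** in three caliber classes mirror the evaluation scheme:
  type 1 are large midline structures (a deep trunk, a superior midline
  arc, a deep posterior vein; radius 3 mm), type 2 are medium branches
  leaving the trunk laterally (radius 2 mm), and type 3 are short thin
  branches just beneath the cortical surface (radius 1 mm). Types 1–2
  are connected to the trunk; type-3 branches are deliberately isolated,
  reproducing the clinically important case of cortical vessels whose
  connectivity is not apparent — pass 1 cannot reach them, pass 2 must.
* **Lesions** are spheres with radius drawn from 0.8–6 mm (maximum
  axial diameter 1.6–12 mm, straddling the 2 mm reporting subgroup),
  placed with a 2-voxel clearance from vessels, other lesions and the
  brain surface.
* **Contrast.** GRE levels: background 0.05, GM 0.35, WM 0.55, vessels
  0.95, lesions 0.85 — vessels and lesions bright, vessels brightest
  (enhancing blood pool). BB levels: vessels at background (0.05),
  lesions 0.82 (enhancing lesions keep their signal on BB; the small
  drop reflects the different sequence contrast), WM/GM 0.48/0.40 —
  the reduced tissue contrast of the fast spin-echo acquisition.
* **Degradations.** Additive Gaussian noise (sd 0.02, clipped to
  [0, 1]) on both channels; Gaussian blur (σ 0.4 voxel) on BB only,
  standing in for the longer acquisition's motion sensitivity; and a
  configurable fraction (default 2%) of vessel voxels left at GRE level
  on BB, emulating imperfect flow suppression (the mechanism behind
  false positives on real BB images). Residual voxels are sampled
  voxelwise so the realized fraction concentrates tightly around the
  target.

What the phantom does *not* emulate: anatomy (gyri, ventricles, skull
stripping difficulty), partial-volume effects at vessel and lesion
boundaries, spatially correlated noise, bias fields, or any pulse
sequence physics. Passing phantom tests therefore demonstrates the
*algorithmic* properties — mask coverage, lesion sparing, contrast
ordering, trainability — not clinical performance; parameters
(`seed_floor`, `residual_threshold`, FCM cluster count) will need
re-examination on real data where intensity histograms are broader.

## Evaluation

`R_s = SI_WM / (0.5 (SI_WM + SI_vessel))` maps complete suppression
(`SI_vessel = 0`) to 2, vessel-equals-WM to 1, and brighter-than-WM
vessels toward 0. On phantoms the nine vessel ROIs are spheres centered
on centerlines of three segments per caliber class and `SI_vessel` is
the mean of the three per-ROI means (not the pooled voxel mean); the WM
reference ROI is drawn in white matter with a clearance check against
vessels and lesions.

Human conspicuity scoring has no phantom analogue, so lesion detection
uses an objective call rule: 26-connected components above
`call_threshold` (default 0.7 — between the WM level 0.55 and the
lesion level ≥ 0.8) of at least `min_size_vox` voxels (default 3),
inside brain tissue and outside the known vessel truth dilated by one
voxel (ring-blended or blurred vessel boundary voxels are vessel
signal, not lesion candidates). A call matches a lesion when its
centroid falls within the lesion radius; lesions match at most once;
extra calls landing on an already-matched lesion are ignored (one
lesion, one detection, as in free-response scoring); all remaining
calls count as false positives (a volume with at least one spurious
call is flagged once for the per-patient view). Sensitivity is reported
overall and for the ≥ 2 mm subgroup. Note
that sub-2 mm lesions occupy a single voxel at 1 mm spacing and fall
below `min_size_vox` — the same regime where the reference modality also
loses sensitivity.

Weighted kappa uses linear agreement weights by default (quadratic
optional; on two categories quadratic weighting reduces to the
unweighted statistic). The degenerate single-category table has chance
agreement 1 and is returned as `NA` with a warning.

## Desk-scale study sizes

The worked end-to-end study trains the 5×16 network on four phantoms
(GRE → synthetic BB), with one validation and two held-out test
phantoms, 90 patches per training volume per epoch (31³, batch 5), 8
epochs at rate 1e-3. These sizes are the package's desk-scale design
point: they keep a full phantom-to-evaluation cycle in the ten-minute
range on one CPU core while leaving the qualitative conclusions —
vessel suppression ratios ordered deep-learned ≫ GRE for every caliber
class, preserved ≥ 2 mm lesions, rare false positives — stable. The
tests assert exactly those directions and floors, not point values: at
a few hundred optimizer steps the quantitative ratios remain
seed-dependent.

One desk-scale limitation deserves naming. The training corpus contains
only a few dozen lesion instances, and with long-enough training the
network begins to fit those instances rather than the generic
"bright compact blob ⇒ preserve" rule: training-set lesions stay
perfectly preserved while the occasional held-out medium (4–6 mm)
lesion — locally similar to a large-caliber vessel cross-section — is
partially suppressed. The epoch budget above ends training while the
generic rule still dominates; the full-scale remedy would be more
training subjects, not more epochs. Data augmentation is deliberately
out of scope.

## Known limitations

* The phantom's crisp labels make FCM clustering nearly trivial; the
  clustering path is stress-tested separately on overlapping Gaussian
  mixtures.
* Registration is rigid (6 DOF, normalized cross-correlation,
  centre-of-mass initialization + multi-resolution Nelder-Mead). It
  recovers the small offsets relevant to same-session brain MRI;
  nonrigid deformation and bias fields are out of scope.
* Brain extraction is Otsu + closing + largest component. It relies on
  a background/tissue intensity gap and a spatial gap between brain and
  any bright rim; it is not a skull-stripping method for real heads.
* The residual unsuppressed-vessel mechanism copies BB's own failures
  into the synthetic label (by construction, as in the underlying
  procedure); the network can only be as clean as its labels on those
  segments.
* Single-precision training: losses below ~1e-7 are at the numerical
  floor of the engine.
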