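---
title: "Methods: post-processing and spatial statistics for soft X-ray tomograms"
author: "sxtcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-processing and spatial statistics for soft X-ray tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sxtcell)
```

`sxtcell` takes over where segmentation networks stop: it assembles
per-slice 2D predictions of a soft X-ray tomogram into 3D organelle
masks, evaluates them, and computes the mesoscale spatial statistics
that the masks exist for. This vignette is the package's own account of
the underlying models and of every numerical choice that was genuinely
open.

## Data model and conventions

A tomogram is a 3D grid of linear absorption coefficient (LAC) values,
axis order (X, Y, Z), canonical post-crop shape 280 × 480 × 320. LAC is
proportional to local molecular density, so organelles appear as
LAC-contrast structures: the nucleus below the cytoplasm, mitochondria
marginally above it (contrast ratio ≈ 1.1), and dense-core insulin
vesicles well above it (LAC ≈ 0.3–0.6, rising toward the core). All
voxel coordinates are 1-based, matching R indexing; distances and radii
are in voxel units. Physical calibration (µm/voxel) is stored on volumes
but never applied implicitly, because source tomograms do not always
carry a trustworthy pixel size.

Masks, instance maps (contiguous labels 1..k over background 0) and the
fused cell scene (codes 0 outside, 1 cytoplasm, 2 mitochondria,
3 nucleus, 4 vesicle) are plain R arrays with light S3 classes; derived
results (instance tables, RDF and LAC profiles, evaluation reports) are
tibbles with `tidy()`/`glance()`/`autoplot()` methods.

## Preprocessing

Slices and patches exist because the segmentation networks upstream
operate on 2D inputs. `slice_volume()`/`stack_slices()` are exact
inverses along each axis. `split_patches()` tiles a slice with patches
(default 150 × 50 pixels, the size used for small-object detection on
280 × 480 slices) on a regular grid with stride
`floor(extent · (1 − overlap))` and the last patch snapped to the
border. The nominal ~30 % overlap is interpreted as a *minimum*: a
regular grid with this stride guarantees deterministic full coverage,
which a literal "about 30 %" does not. Border patches are clipped rather
than padded — padding would fabricate intensities. When merging scored
patch predictions, the higher score wins per pixel and ties go to the
lower patch index, making the merge deterministic.

`resize_volume()` uses center-aligned trilinear interpolation for
intensities and nearest-neighbor for labels (so the label alphabet can
only shrink). Cropping takes an explicit box; detecting the glass
capillary walls that motivate the crop is out of scope.

## The three fusion algorithms

**Multi-view voting.** Semantic masks predicted independently along X,
Y and Z are combined per voxel by majority: foreground iff at least two
views agree. The rule is symmetric in the views, idempotent under
unanimity, and bounded between the intersection and the union of the
views — properties the test suite checks against a per-voxel oracle.
With independent view errors, voting strictly reduces the error rate,
which is why the fused Dice beats the best single view in the
degradation experiments.

**2D→3D instance linking.** Individual vesicles are predicted per
slice; instances on adjacent slices are merged when the IoU of their 2D
footprints is *strictly greater than* 0.5 (IoU is computed on the full
footprints, not bounding boxes). Choices the rule itself does not fix:

* *One-to-one chaining.* When one instance exceeds the threshold
  against several candidates, it links only to the highest-IoU one
  (ties to the lower label). Transitive but one-to-one chains prevent
  uncontrolled merging of touching vesicles.
* *No gap bridging.* An instance missing from one slice terminates its
  chain; with ~25 nm voxels a one-slice gap is a real discontinuity
  more often than a prediction dropout.
* *Single axis.* Linking runs along the axis used for instance
  prediction (X); multi-view fusion is applied only to semantic masks.

Note that geometric solids always violate the premise at their tips: the
last cross-section of a sphere is much smaller than its neighbor, so
polar caps can split off as separate instances. This affects AP-style
counts, not distance-based recall, and is inherent to any slice-linking
rule with a fixed threshold.

**Priority merging.** The per-class masks are merged into one scene
under vesicle > nucleus > mitochondria > cell; a voxel gets the
highest-priority class that claims it, so vesicle voxels are never
overwritten and cell-only voxels become cytoplasm. The rule is applied
literally: organelle voxels outside the cell mask keep their organelle
code and are only *reported* by `scene_qc()`, not silently clipped —
clipping would hide upstream segmentation errors from the user.

## Evaluation metrics

Dice and IoU are standard; `dice = 2·IoU/(1 + IoU)` is asserted as a
cross-check. Instance recall uses the normalized center distance
`d = d_u/(r_pred + r_gt)` with equivalent-sphere radii
`r = (3n/4π)^{1/3}`; a pair with `d < 1` is a true positive. Radii are
3D because matching operates on fused 3D instances (a per-slice 2D
reading of the same criterion would need a slice-matching rule the
pipeline never defines). Matching is greedy over pairs sorted by
ascending `d`, one-to-one; for separated instances this equals the
optimal assignment (checked against exhaustive enumeration on small
scenes) and it is deterministic. AP50 follows the standard single-class
all-point-interpolated convention with mask IoU ≥ 0.5, descending
scores, ties broken by label.

The contrast ratio of an organelle is computed slice-wise along X: each
slice is normalized by its own maximum, and the mean normalized
intensity over organelle pixels is divided by the mean over a
surrounding shell. The surround is not defined by the quantity itself,
so it is a parameter: the default is a 2-voxel dilation shell restricted
to admissible context (cytoplasm with other organelles excluded).
Because both means are taken within one slice, the ratio is invariant to
the per-slice normalization — the normalization matters only when
intensities are compared *across* slices or cells.

## Shells and radial distribution functions

The cytosol (inside cell, outside nucleus) is partitioned into 8
concentric shells by the normalized depth
`λ = d_nuc/(d_nuc + d_pm) ∈ (0, 1)`, where `d_nuc` and `d_pm` are exact
Euclidean distance transforms to the nucleus and to the outside of the
cell. Shell k collects `λ ∈ [(k−1)/8, k/8)`. Relative depth rather than
absolute distance is the default because it normalizes the space in all
directions: a vesicle halfway between the membranes lands in the same
shell whether it sits in a squeezed or a bulging lobe of an irregular
cell. For a spherical cell the shells reduce to spherical annuli of
equal relative thickness.

The RDF of a population over the shells is

g_k = (count_k / V_k) / (N / V),

with V_k the shell volume and V the cytosol volume. The empirical
shell-volume normalization replaces the spherical `4πr²` factor of the
textbook pair-correlation definition; it is exact for arbitrary cell
shapes and reduces to `4πr²·dr` in the spherical limit. By construction
the volume-weighted mean of g is 1, and uniform random placement gives
g ≈ 1 in every shell — the baseline against which enrichment is read.
Three population types are supported: instance centers (vesicles),
voxels (mitochondria), and contact centers. A vesicle's "center" is its
geometric centroid for the RDF; the max-LAC voxel (the dense-core peak)
is a different notion of center used by the LAC profiles — both are
exposed because they answer different questions.

A contact is a 26-connected component of vesicle voxels within 1.5
voxels (Euclidean, strict) of the mitochondria surface; 26-connectivity
is chosen because contact patches are thin diagonal shells that
6-connectivity would fragment. Contact monotonicity in the cutoff and
equivalence with an all-pairs distance scan are tested.

Per-vesicle LAC profiles bin instance voxels by interior distance to
the instance boundary (1-voxel bins; a voxel adjacent to the outside has
distance 1) and report the mean LAC per bin; the dense-core property
appears as a non-decreasing profile from boundary to center.

## The phantom generator

No public tomograms or network weights accompany this problem, so the
generator is a first-class module, not a fixture: it defines the study
conditions under which every claim of the package is tested.

* Geometry: one ellipsoidal cell (semi-axes ≈ 40 % of each extent,
  ±5 % jitter), one off-center ellipsoidal nucleus (60 % of the cell
  semi-axes, offset 22 % toward a random direction — nucleus/cell
  volume ratio ≈ 1/3, as in the tomograms this emulates), tubular
  mitochondria as random capsules, and spherical vesicles of radius
  3–6 voxels packed without overlap into the free cytosol.
* LAC levels: background 0.10, nucleus 0.22, cytoplasm 0.30,
  mitochondria 0.3335 (contrast ratio ≈ 1.11 over cytoplasm, the
  realistic low-contrast regime that makes mitochondria hard to
  segment), vesicles rising linearly from 0.35 at the rim to 0.55 at
  the core — inside the typical 0.3–0.6 vesicle range. Gaussian voxel
  noise with sd 0.02 is added and values are clamped at 0.
* Default shape 140 × 240 × 160 (half canonical), so a phantom plus its
  distance fields build in a few seconds; tests use smaller shapes
  (≈ 64 × 96 × 72) to keep the whole suite under a minute of phantom
  time.

All randomness flows through one seeded generator per call
(`withr::local_seed`); the same seed reproduces a phantom bit-exactly.

What the phantom deliberately does **not** emulate: SXT projection
physics, missing-wedge reconstruction artifacts, the capillary geometry,
textured organelle interiors, and touching vesicle clusters. Passing
tests therefore certify the *post-processing and statistics*, not
network-grade robustness on real tomograms. Two phantom-specific
artifacts are worth knowing: packed spheres cannot occupy the thinnest
shells, so ground-truth vesicle RDFs dip at shells 1 and 8; and the
threshold backend captures only vesicle cores, reproducing the
real-world pattern of high distance-based recall with low voxel overlap.

`degrade_views()` corrupts a mask three times independently (boundary
jitter, false-negative dropout, false-positive speckle) to exercise the
voting fusion; `threshold_segment()` (box smoothing + LAC banding +
connected components, small components discarded) provides an honest,
deliberately simple end-to-end backend.

## Numerical choices and degenerate inputs

* Distance transforms are exact squared-distance transforms
  (lower-envelope algorithm), not chamfer approximations, because the
  1.5-voxel contact cutoff and the `d < 1` matching rule sit close to
  the 1–2 voxel scale where chamfer errors bite.
* IoU/Dice of two empty masks, an empty ground-truth set, an all-zero
  slice, an empty crop box and an empty instance are errors, not NaNs —
  silent NaN propagation is how batch analyses rot.
* An empty contact set is a *result* (empty tibble, g undefined and
  flagged as NA), because "no contacts" is biology, not a failure.
* Label maps are relabeled to contiguous 1..k on ingest so instance
  identities are stable across linking, matching and RDF.
* TIFF stores unsigned 16-bit (intensities as fixed point over [0, 1]);
  MRC mode 2 stores 32-bit floats and is the format of choice for LAC
  volumes. Round trips are lossless at the stored precision.

## Acceptance computation

`scripts/acceptance.R` re-derives the package's self-contained
quantitative target: with 1,000 uniformly placed centers per phantom
cytosol and 20 seeded replicates (20,000 draws), every shell's mean g
must sit within ±0.1 of the uniform baseline 1.0; the script reports the
shell farthest from 1. The problem size (half-canonical phantoms,
20 × 1,000 draws) was chosen so the per-shell standard error of the mean
(≈ 0.02–0.04 depending on shell volume) resolves a 0.1 deviation with
a wide margin.

## Known limitations

* Instance linking cannot separate vesicles that overlap in-plane with
  IoU > 0.5 across many slices, and splits polar caps of elongated
  solids (see above).
* The contrast-ratio surround and the AP50 interpolation convention are
  parameterized/standardized choices; other conventions will move the
  numbers by a few percent.
* Absolute-distance shell binning (as opposed to normalized depth) is
  not currently exposed; for strongly non-convex cells normalized depth
  is the defensible default, and mode-tagging results was deferred
  until a second mode exists.
* The CLI covers the pipeline stages one subcommand at a time; batch
  orchestration across many tomograms is left to the caller.
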