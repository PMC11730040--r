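---
title: "Sizing and MARS rating of cerebral microbleeds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing and MARS rating of cerebral microbleeds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmbmars)
```

Cerebral microbleeds (CMBs) are compact, roughly spherical hemosiderin
deposits of 2–10 mm seen on susceptibility-weighted MRI. Automated
segmentation pipelines deliver binary CMB maps; the clinically useful output,
however, is a *characterisation*: each lesion's diameter and its anatomical
position in the scheme of the Microbleed Anatomical Rating Scale (MARS),
which counts CMBs per structure and aggregates them into three regions —
infratentorial, deep and lobar. This vignette explains the models and the
design decisions behind each stage of the package, and what the synthetic
phantom tests do and do not establish.

## The volume container and orientation

All volumes (masks, probabilistic atlases, label maps) are `cmb_volume`
objects: a 3D array plus voxel dimensions in mm and a 4×4 voxel-to-world
affine in the NIfTI convention (0-based voxel coordinates). On load,
`canonicalise_orientation()` permutes and flips the voxel axes so that each
aligns with the anatomical axis it predominantly points along (the
right-handed RAS convention of MNI standard space). The reorientation is
derived from the affine's dominant directions and compensated in the affine
itself, so every voxel centre keeps its world position; the operation is
idempotent, and downstream code can assume a single axis convention.

## Lesion extraction

`label_components()` partitions the mask foreground into maximal connected
components. The default connectivity is 26 (faces, edges and corners):
CMBs are compact blobs, and stricter connectivities can split a lesion whose
voxels touch only diagonally; 6 and 18 remain available for sensitivity
analyses. Component ids follow the raster-scan order of first encounter,
making the output deterministic. The centroid is the per-axis arithmetic mean
of voxel indices, with an mm version scaled by the voxel dimensions.

## The moment-matched diameter

The diameter of a lesion is defined through the uniform-density solid
ellipsoid with the same second-order central moments — the same spread and
orientation — as the lesion's voxel set. Voxel coordinates are scaled to mm
*before* computing moments, so anisotropic grids are handled by construction
rather than by a single post-hoc scale factor. Two numerical choices matter:

* **Per-voxel self-extent.** Each voxel is a little cube of side $d_a$, not a
  point; its own central second moment, $d_a^2/12$ per axis, is added to the
  covariance diagonal. Without this term a single-voxel lesion would have
  zero spread and small lesions would be systematically undersized. With it,
  a single 1 mm voxel measures $2\sqrt{5/12} \approx 1.29$ mm — the diameter
  of the ball with the same second moment as a unit cube.
* **The ellipsoid constant.** A solid ellipsoid of semi-axis $a$ has central
  second moment $a^2/5$ along that axis, so the major-axis length is
  $2\sqrt{5\lambda_{\max}}$ with $\lambda_{\max}$ the largest covariance
  eigenvalue. (Using the surface or the bounding box instead would change the
  constant; the solid-body reading matches the physical object.)

The result is floored at `max(voxel_dims)` — no lesion can be narrower than
one voxel — and reported unclipped above 10 mm, with an `oversize` flag:
whether to exclude such lesions (often vessel fragments picked up by the
segmentation) is an inclusion policy that belongs to the caller, not to the
measurement.

### The calibration lesion

Digitised spheres carry quantisation error: a voxelised ball of 6-voxel
extent measures about 6.5 voxels by moments, because the discrete set holds
slightly more mass at its extremes than the continuous ball. Tests of the
*scaling* step therefore use `calibration_lesion()`, a 30-voxel blob whose
moments are known exactly: slab counts (1, 8, 6, 6, 8, 1) along the axis give
discrete variance $103/60$; adding the $1/12$ self-extent yields
$1.8 = (6/2)^2/5$ voxel², i.e. a moment-matched major axis of exactly
6 voxels, while the sign-symmetric transverse patterns keep the covariance
diagonal and the transverse variances well below the axial one. On a 0.9 mm
grid the estimator hence returns exactly $6 \times 0.9 = 5.4$ mm. For real,
voxelised spheres the accuracy claim is the quantisation bound: radii of 2–8
voxels are recovered within one voxel (verified across isotropic and
anisotropic grids in the test suite).

## Building the MARS atlas

`mars_lut()` encodes the thirteen MARS structures, their regions and their
usual sources: Harvard-Oxford subcortical probabilities for brainstem, basal
ganglia, thalamus (threshold 50) and deep white matter (threshold 60); MNI
structural labels for cerebellum and the cortical lobes; JHU ICBM-DTI-81
labels for the capsules and corpus callosum. Probabilistic sources are
binarised with an *inclusive* threshold on the percent scale (a uniform map
at exactly 50 thresholded at 50 stays foreground — the common atlas-tool
convention; unit-scale maps are detected from the data maximum and the
threshold rescaled).

Assembly applies, in order:

1. **Lobar dilation** — cortical lobe masks are dilated with a 3×3×3 cube
   ("size 3" most plausibly names the element's width; ball and cross shapes
   are selectable) so the grey-white junction counts as lobar.
2. **White-matter exclusion** — capsule and corpus callosum voxels are
   removed from the deep white matter mask, since they are rated separately.
3. **Priority** — overlaps across classes resolve as infratentorial > named
   deep structures > deep white matter > dilated lobar. The rationale: the
   dilation exists solely to extend the cortex outward, so it must never
   annex deep or infratentorial tissue.
4. **Ties within a class** (e.g. two dilated lobes meeting in a sulcus) go to
   the structure whose *undilated* mask is nearest (Euclidean distance in
   mm); exact ties to the lower structure code. This makes the label volume a
   deterministic function of its inputs.

`transform_atlas()` carries the atlas into a subject grid through a supplied
world-to-world affine: each structure mask is pulled through the inverse
affine with trilinear interpolation, thresholded at 0.5, and re-assembled
under the same priority rules (without re-dilating). Estimating the
registration is out of scope — the affine comes from the user's registration
tool, and `read_affine()` converts the FSL/FLIRT scaled-voxel dialect to the
world convention when asked.

## Rating

`rate_subject()` chains components → centroids → diameters → structure
assignment → aggregation. Assignment rounds the centroid to the nearest voxel
(halves away from zero) and reads the label there; rounding in voxel index
space is used because the atlas lookup is voxelwise. Lesions whose centroid
lands on background are reported as `unclassified` rather than dropped or
force-assigned — silent reassignment would corrupt the MARS counts. For
lesions straddling a boundary a majority-vote mode (`method = "majority"`)
assigns by the most frequent label over all lesion voxels. Region counts are
a pure aggregation of structure counts; `total` always equals structure
counts plus unclassified, and these invariants are asserted in tests.
Left/right lateralisation of the full MARS form is not modelled (counts are
bilateral), though a lateralised LUT would work without code changes.

## Evaluation

`evaluate_subject()` compares a predicted mask with a manual reference at
lesion level. Matching is greedy one-to-one by descending voxel overlap
(≥ 1 voxel), ties by centroid distance then id; on well-separated lesions
this equals the exhaustive optimal assignment, which the test suite verifies
by brute force over permutations on instances with up to six lesions per
side. A centroid-distance criterion (default 5 mm) is available for masks
whose lesions may not overlap.

Region metrics are lesion-level: a matched lesion is a region TP when both
sides place it in the same region; reference lesions missed entirely, or
placed elsewhere by the prediction, count as FN; predicted lesions with no
manual counterpart enter precision through their automated region only.
Overall accuracy is the fraction of matched lesions with agreeing region
labels. A count-level mode (`TP_R = min(pred, ref)` per region) supports
references that provide only MARS subscores without masks. Confusion
matrices (manual rows, automated columns) and the false-negative histogram
are computed over the same matching, so all marginals are mutually
consistent — an invariant the tests check against independently computed
ratings. Reports print metrics to 2 decimals and sizes to 1 decimal.

## The synthetic phantom

`phantom_spec()` describes a scene: geometric primitives (balls and boxes)
standing in for the thirteen structures, plus digitised spherical lesions
with known centres, diameters (constrained to 1–12 mm) and intended
structures. The default grid is 64³ at 0.9 mm isotropic — large enough to
hold all structures as disjoint primitives with clearance, small enough for
sub-second generation. Probability maps render each primitive at 100 inside
with a linear falloff to 0 over two voxels outside, so thresholding at 50
recovers the primitive to within one voxel. `perturb_mask()` degrades a
ground-truth mask per lesion — Gaussian mm jitter, random drop (false
negatives), or erode/dilate (size errors) — deterministically for a fixed
seed.

What the phantoms establish: exactness of the moment arithmetic, the
quantisation bound for sphere recovery, 100% assignment for lesions placed
at least two voxels inside their structure, count conservation, binomial
calibration of the evaluation under `drop(p)` (the observed false-negative
fraction across 200 seeded phantoms stays within three binomial standard
errors of p), and the atlas assembly/transfer oracles. What they do not
establish: performance on real SWI-derived masks — real lesions are not
spheres, real structures are not boxes and balls, registration error and
rater variability are absent, and no susceptibility physics is simulated.
Accuracy figures on clinical data therefore require clinical masks and
manual ratings; the phantom results bound only the algorithmic, not the
biological, error.

## Problem sizes and runtime choices

Defaults were chosen to keep the full test suite fast on one CPU: 64³ phantom
grids for pipeline tests, 32³ grids with six lesions for the 200-phantom
calibration study, sphere radii 2–8 voxels, and brute-force matcher checks at
≤ 6 lesions per side (720 permutations). These sizes are stated here as the
package's own study conditions; all of them are set in the tests and can be
scaled up by the user.

## Known limitations

* Masks are taken at face value: no vessel-fragment cleanup, no
  definite/possible CMB grading (that needs intensities and rater judgment).
* The affine is applied, never estimated; non-linear warps are not supported.
* Centroid-based assignment is sensitive near structure boundaries; the
  majority-vote mode mitigates but cannot remove this (boundary lesions are
  genuinely ambiguous).
* Third-party atlases are not shipped; users supply their own volumes (the
  LUT tells the package how to binarise them), or use the phantom generator.
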