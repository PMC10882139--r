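---
title: "TPDM reconstruction from multi-directional MIPs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TPDM reconstruction from multi-directional MIPs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpdmr)
```

## The model

A tumor probability distribution map (TPDM) is a 3D prior for whole-body
PET lesion segmentation built from 2D lesion segmentations of maximum
intensity projections (MIPs). The underlying geometric idea is that of a
visual hull: a lesion visible in a 2D projection constrains its 3D position
to the shadow of that projection; intersecting shadows from many directions
localizes it. Formally, for angles $\theta_k = k \cdot 180^\circ/n$,
$k = 0, \dots, n-1$, and per-angle binary masks $M_k$ on the projection
plane, the raw map is

$$ R(v) \;=\; \sum_{k=0}^{n-1} M_k\big(\pi_{\theta_k}(v)\big), $$

where $\pi_{\theta}$ traces voxel $v$ to its pixel in the $\theta$-rotated
frame (the z row is preserved; the column is the rotated in-plane
coordinate). $R(v) \in [0, n]$ counts the supporting projections. The
half-open angle family over $[0^\circ, 180^\circ)$ suffices because
projections at $\theta + 180^\circ$ are mirror images.

Post-processing turns the count volume into the prior:
$T(v) = R(v)\cdot \min(\mathrm{SUV}(v), 5)$, normalized by $\max_v T(v)$,
followed by zeroing all voxels at or below the 5th percentile of the
strictly positive values. The SUV gate at 5 gives similarly-weighted
evidence across lesions (clinical uptake in lesions usually exceeds 5)
while multiplicatively suppressing streak artifacts that fall on
low-uptake tissue; the percentile cut removes the residual noise floor.

## Numerical construction and its invariants

Projection is implemented as rotate-then-axis-max rather than ray casting,
and backprojection as replicate-then-rotate-back, so the two paths are
exact adjoints on the voxel grid. Three numerical decisions make the
pipeline's central guarantee *exact* rather than approximate:

* all projections and backprojections of a case share one frame — the
  in-plane grid resampled to isotropic spacing (min of the two in-plane
  spacings, so rotation never shears) and zero-padded to the ceiling of the
  in-plane diagonal (so no intensity leaves the frame at any angle);
* rotation uses inverse-mapping interpolation about the padded frame
  center, positive angles counter-clockwise viewed from +z; intensities are
  interpolated bilinearly within each axial slice, masks and labels with
  nearest neighbor so they stay binary;
* the forward label projection and the backprojection use the *same*
  nearest-neighbor rounding, which yields the coverage theorem the tests
  assert: every ground-truth voxel whose in-plane 8-neighbors are also
  ground truth reaches the full count $R(v) = n$ with oracle masks. (The
  rounding argument: the backprojection lookup for $v$ lands on the padded
  grid point nearest $R_\theta v$; un-rotating that point lands within one
  in-plane voxel of $v$, so an interior voxel always finds labeled support.)

Consequences checked as properties in the suite: $\max R \le n$ always;
the maximal-count core $\{R = n\}$ shrinks (never grows) on nested angle
sets; the binarized support of the post-processed map contains essentially
all ground-truth voxels (the percentile cut can only remove voxels whose
product value sits in the bottom 5% of positives, which lesion voxels —
high count × gated SUV — do not reach on the phantom conditions).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_angles` | 36 | — | 5° interval over [0°, 180°); the saturation regime of the projection-count study |
| `suv_clip` | (0, 15) | SUV | standard display/normalization window for whole-body FDG PET |
| `ct_clip` | (−100, 250) | HU | soft-tissue window for the anatomy channel |
| `mr_clip` | (0, 1000) | a.u. | water-fraction MR intensity window |
| `tpdm_suv_clip` | (0, 5) | SUV | evidence gate: lesion uptake is usually > 5, so most lesion voxels weigh equally |
| `percentile_cut` | 5 | % | fraction of positive TPDM intensities treated as noise floor |
| `crop_margin` | 2 | voxels | margin around the joint foreground box |
| `patch_size` | (160,160,160) | voxels | sliding-window patch for the downstream 3D segmenter |
| `patch_overlap` | 0.25 | — | fraction of shared planes between consecutive patches (stride `floor(160·0.75) = 120`) |
| `tau` (binarize) | 0 | — | support of the prior |
| `tau` (study) | 0.5 | — | half-maximal evidence; see below |

Normalization is the fixed affine map over the stated clip window, not
per-volume min–max: it is deterministic, idempotent and comparable across
patients. Resampling fills out-of-extent regions with −100 HU for CT and 0
for SUV/MR so that subsequent clipping maps them to the normalized floor.
Foreground cropping uses the union criterion (SUV > 0 *or* anatomy above
its clip floor) with a joint box across channels, since a per-channel box
would break voxel correspondence.

## Design choices where the design was open

**Binarization threshold for the projection-count study.** `binarize_tpdm()`
defaults to `tau = 0`, the full support — the natural object when the TPDM
is consumed as a prior. For the HD95-vs-projection-count study, however,
the support is the union of SUV-gated shadows, which can only grow with
the number of angles; measured at `tau = 0` the curve cannot decrease on
any phantom with positive background uptake. The study therefore defaults
to `tau = 0.5`: on the max-normalized map this is "half-maximal accumulated
evidence", a scale-free criterion (a voxel needs support from about half
the projections regardless of $n$), under which single-angle streaks and
hot-spot crossings drop out as $n$ grows. Under the default phantom
conditions with *oracle* masks the curve is flat from $n = 1$: SUV gating
alone already removes all streaks, so TPDM quality saturates immediately.
The characteristic sharp-decrease-then-saturate shape belongs to the
regime of imperfect 2D masks, where single-angle false positives need
several angles to be voted out; the monotone non-increase and the 18-vs-36
saturation are what the acceptance suite asserts.

**Percentile semantics.** The cut is computed over *strictly positive*
voxels (over all voxels, the background zeros would make a 5th percentile
vacuous) with R's linear-interpolation quantile, and voxels *equal* to the
cut value are removed ("bottom percentile" read inclusively). On a map
with ≥ 10^5 distinct positive values this zeroes 5% of positives to within
a few parts in 10^5, which is what the acceptance target measures.

**SUV source for the gate.** The raw map is multiplied by the
*un-normalized* SUV clipped to [0, 5], not by the [0, 15]-normalized
channel: the gate's rationale (lesion uptake usually above 5) refers to
physical SUV units.

**Lesion-wise metrics.** Components use 18-connectivity (faces + edges,
corners excluded); the > 0.5 ml volume filter is applied to both prediction
and ground truth before matching (configurable to prediction-only), and
detection overlap is tested against the counterpart's *raw* foreground so
that a filtered-out sliver cannot undo a detection. Both-empty Dice
returns 1 with an explicit flag; sensitivity with no ground-truth lesions
and precision with no predictions are `NA`, never silently 0 or 1. HD95
uses boundary voxels (foreground with a background 6-neighbor), physical
mm distances, pooled symmetric directed distances and the interpolated
95th percentile; empty masks give `NA` with a warning.

**Wilcoxon signed-rank.** Zero differences are dropped; for effective
$n \le 12$ the two-sided p-value comes from exhaustive enumeration of all
$2^n$ sign assignments of the tie-averaged ranks (correct under ties);
above that, a normal approximation with tie and continuity correction.
The exact branch is validated against full enumeration and against
`stats::wilcox.test` on tie-free data.

**Indexing.** All public indices are 1-based with inclusive start/stop
bounds (crop records, patch origins), the R convention.

## The synthetic phantom: what it emulates, what it does not

`phantom_spec()`/`generate_phantom()` build a body ellipsoid with
soft-tissue background uptake (default SUV 1.0), ellipsoidal lesions with
a cosine-tapered profile peaking at the declared SUVmax (the center voxel
samples the peak exactly, so the truth table is realized on the grid),
physiological hot spots excluded from ground truth (brain-like and
bladder-like spheres at the body's extremes — false-positive stressors for
the SUV gate), and truncated Gaussian noise inside the body. Defaults are
chosen once to mirror a lymphoma-like whole-body cohort digitized at
(2.04, 2.04, 3.00) mm: lesion count ~ round N(7, 2) clamped ≥ 1, peak SUV
~ N(8.88, 4.84) truncated below at 2 (so a realistic fraction of
low-uptake lesions with SUVmax < 4 appears), and 40% small lesions with
MTV < 2 ml — the regime where a prior matters most clinically.

The phantom validates the *geometry and arithmetic* of the pipeline:
projection/backprojection consistency, accumulation counts, gating,
percentile behavior, metric definitions. It does not emulate attenuation,
scatter, partial-volume blur, textured uptake, respiratory motion or
realistic anatomy; a passing suite therefore says the machinery is
correct, not that any particular 2D segmenter will perform well on
clinical data. Cohort-level clinical performance requires real scans and
trained networks and is explicitly outside the package's claims.

## Problem sizes and reproducibility

The test and acceptance workloads use 64³ cohort cases (20 cases for the
coverage/sensitivity properties, 6 for the projection-count study), a 112³
fixed-geometry phantom for the percentile measurement (≥ 10^5 distinct
positive product values), and the full 280³ volume for the patch
arithmetic — sizes at which every property is measurable on a single CPU
in minutes. All randomness (phantom sampling, noise, noisy-oracle
segmenter) flows through explicit integer seeds via `withr`, and
accumulation is angle-sorted and sequential, so identical configurations
reproduce bit-identical volumes.

## Known limitations

* Rotation-based projection assumes the axial axis is the third array
  axis and in-plane isotropy after the frame resample; oblique
  acquisitions must be reoriented upstream.
* Backprojection with nearest-neighbor rounding is exact for coverage but
  dilates mask boundaries by up to one in-plane voxel per angle; contours
  in the raw map are intentionally blurry, and sharpening is delegated to
  the SUV gate and the downstream segmenter.
* `hd95()` uses chunked exact nearest-neighbor distances between boundary
  point sets; it is intended for masks up to a few hundred thousand
  boundary voxels, not for dense million-voxel surfaces.
* The Wilcoxon normal approximation is the classic large-sample form; for
  13–20 pairs with heavy ties an exact permutation approach would be
  preferable (set `exact_max` higher to force enumeration up to ~20 at
  exponential cost).
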