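# tpdmr — tumor probability distribution maps for whole-body PET lesion segmentation

Automated tumor segmentation in whole-body <sup>18</sup>F-FDG PET/CT and
PET/MRI is hard because lesions vary enormously in size, shape, uptake and
location, and small lesions are easily missed by 3D segmentation networks
working directly on the volume. `tpdmr` builds a **tumor probability
distribution map (TPDM)** — a 3D segmentation prior on the PET grid —
from lesion segmentations of **multi-directional 2D maximum intensity
projections (MIPs)**, the view nuclear-medicine readers actually use for
lesion spotting.

The construction has three stages:

1. **Projection.** The SUV volume is rotated about the axial (head–foot)
   axis to angles θ<sub>k</sub> = k·180°/n, k = 0…n−1 (default n = 36, i.e. a
   5° interval over [0°, 180°); the remaining half-circle contains only
   mirror images) and a MIP is taken along the fixed in-plane axis at each
   angle. Any 2D lesion segmenter can be plugged in per angle: the package
   ships an oracle (ground-truth projections), a classical SUV-threshold
   segmenter, a noisy oracle for robustness studies, and an `external` kind
   that reads per-angle masks produced by any trained network.
2. **Backprojection.** Each binary 2D mask is smeared back along its
   projection direction and the n shadow volumes are summed voxel-wise, so
   regions where shadows intersect accumulate evidence up to n. The raw map
   is then **post-processed**: multiplied voxel-wise by the SUV volume
   clipped to [0, 5] (lesion uptake is usually above 5, so most lesion
   voxels get similar weight while low-uptake streak artifacts are
   suppressed), normalized to [0, 1] by the global maximum, and the bottom
   5th percentile of the strictly positive intensities — mostly residual
   streak noise — is set to zero.
3. **Prior injection.** The TPDM joins the normalized anatomy (CT/MR) and
   SUV channels as the third input channel of a downstream 3D segmenter;
   `extract_patches()` produces the standard sliding-window 160³ patches at
   0.25 overlap.

The package also implements the full evaluation suite used in this setting —
Dice, FNA/FPA for 2D projections, HD95, lesion-wise TP/FN/FP with
sensitivity and precision (18-connectivity components, > 0.5 ml volume
filter), MTV, SUVmax, Pearson correlation of patient-wise MTV, and the
paired Wilcoxon signed-rank test — plus a synthetic whole-body phantom
generator so every stage is testable without clinical data or trained
networks.

## Worked example

```r
library(tpdmr)

# a reproducible synthetic whole-body case: 7 lesions, brain/bladder-like
# hot spots, soft-tissue background SUV 1, Gaussian noise
spec <- sample_cohort(1, dims = c(64, 64, 64), seed = 42)[[1]]
ph <- generate_phantom(spec)
ph$truth
#> # A tibble: 7 x 3
#>   lesion mtv_ml suvmax
#>    <int>  <dbl>  <dbl>
#> 1      1  1.52    6.53
#> 2      2  4.38    8.59
#> 3      3  6.87   18.9
#> 4      4  0.662   8.11
#> 5      5  1.12    2
#> 6      6  1.80    8.47
#> 7      7 35.6     9.57

# full pipeline with the oracle 2D segmenter and 36 projections
case <- run_case(ph$suv, ph$anat, ph$gt, pipeline_config(n_angles = 36))
case$tpdm
#> <tpdm> 64 x 64 x 64 voxels, spacing (2.04, 2.04, 3) mm, axes axial-z
#>   value range [0, 1]

# how good is the prior itself? binarize its support and evaluate
mask <- binarize_tpdm(case$tpdm, tau = 0)
evaluate_segmentation(mask, ph$gt, suv = ph$suv, case_id = "phantom-42")
#> # A tibble: 1 x 12
#>   case_id     dice hd95_mm    tp    fn    fp sensitivity precision mtv_ml
#> 1 phantom-42 0.125    39.1     7     0     0           1         1   781.
```

Read the row as a statement about the *prior*, not a final segmentation:
all 7 lesions are detected (sensitivity 1, no lesion-wise false positives),
while the voxel-wise Dice of the raw support is low (0.125) because the
support deliberately over-covers — it is the accumulated shadow evidence
handed to the 3D segmenter, which carves out the final contours. The
post-processing provenance records that 5.0% of the 65,815 positive voxels
were removed by the percentile noise cut (`case$tpdm$provenance`).

A projection-count study (TPDM-vs-truth HD95 for n ∈ {1, 2, 4, 9, 18, 36})
is one call:

```r
cases <- lapply(sample_cohort(6, seed = 21), generate_phantom)
st <- projection_count_study(cases)
st$summary      # mean HD95 per projection count
autoplot(st)    # per-case and mean curves
```

## Command line

A thin CLI over the same functions lives at `inst/cli/tpdm.R`:

```sh
Rscript inst/cli/tpdm.R phantom --out case1 --dims 64 --seed 3
Rscript inst/cli/tpdm.R run --suv case1/suv.nii.gz --anat case1/anat.nii.gz \
    --gt case1/gt.nii.gz --segmenter oracle --out run1
Rscript inst/cli/tpdm.R evaluate --pred run1/mask.nii.gz --gt case1/gt.nii.gz
```

Subcommands: `phantom`, `preprocess`, `project`, `reconstruct`, `evaluate`,
`study`, `run`. All volumes are NIfTI-1; tabular outputs are CSV; manifests
and provenance are JSON.

## Scope

The 2D and 3D segmentation *networks* are deliberately out of scope: the
package's contract ends at per-angle masks in (any producer) and
channel-stacked patches out (any consumer). The phantom generator emulates
lesion statistics, physiological hot spots and background uptake, not
anatomically realistic bodies; see the methods vignette
(`vignettes/tpdm-methods.Rmd`) for what that does and does not validate.
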