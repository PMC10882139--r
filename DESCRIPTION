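Package: tpdmr
Title: Tumor Probability Distribution Maps from Multi-Directional PET Maximum
    Intensity Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tumor probability distribution maps (TPDMs) as 3D
    segmentation priors for whole-body PET/CT and PET/MRI lesion segmentation.
    Generates multi-directional 2D maximum-intensity projections (MIPs) of SUV
    volumes about the axial axis, backprojects 2D lesion masks into a 3D
    accumulation volume, and applies SUV-gated post-processing (clipping,
    normalization, percentile noise removal) to obtain a prior in [0, 1] on the
    PET grid. Includes NIfTI volume I/O and pre-processing (SUV conversion,
    resampling, foreground cropping, clipping/normalization, padding), pluggable
    2D segmenters (oracle, SUV threshold, noisy oracle, external masks), a full
    voxel-wise and lesion-wise evaluation suite (Dice, FNA/FPA, HD95,
    18-connectivity lesion detection, MTV, SUVmax, Pearson correlation, Wilcoxon
    signed-rank), a synthetic whole-body phantom generator, and an end-to-end
    pipeline with sliding-window patch extraction for downstream 3D networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    dplyr,
    ggplot2,
    igraph,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
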