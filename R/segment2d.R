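#' Pluggable 2D lesion-segmenter specification
#'
#' The 2D segmentation stage is a contract, not a fixed model: any per-angle
#' binary mask producer can drive the reconstruction. Four kinds are provided:
#'
#' * `"oracle"` — returns the ground-truth projections verbatim (upper bound,
#'   used for reconstruction-fidelity studies).
#' * `"threshold"` — classic SUV thresholding of the MIP (default SUV 2.5, the
#'   conventional lesion cutoff) with small 2D components removed.
#' * `"noisy_oracle"` — the oracle degraded by per-angle component misses and
#'   injected square false-positive blobs, for robustness studies.
#' * `"external"` — reads pre-computed per-angle masks from disk, so masks
#'   produced by any trained network can be plugged in without this package
#'   depending on a learning framework.
#'
#' @param kind one of `"oracle"`, `"threshold"`, `"noisy_oracle"`, `"external"`.
#' @param threshold SUV threshold for the `"threshold"` kind (> 0).
#' @param min_area_cm2 2D components with area strictly below this (cm^2) are
#'   removed by the `"threshold"` kind.
#' @param miss_prob per-angle probability that each true 2D component is
#'   deleted (`"noisy_oracle"`).
#' @param blob_rate Poisson mean number of injected false square blobs per
#'   angle (`"noisy_oracle"`).
#' @param blob_side side length of injected blobs in pixels.
#' @param seed integer seed making `"noisy_oracle"` reproducible.
#' @param mask_dir directory of per-angle mask files for `"external"`; files
#'   are matched by angle index (`mask_000.png` / `mask_000.nii.gz`, ...).
#' @return a `segmenter_spec` object.
#' @export
segmenter_spec <- function(kind = c("oracle", "threshold", "noisy_oracle", "external"),
                           threshold = 2.5, min_area_cm2 = 0,
                           miss_prob = 0, blob_rate = 0, blob_side = 5,
                           seed = 1L, mask_dir = NULL) {
  kind <- match.arg(kind)
  if (threshold <= 0) stop("`threshold` must be positive (SUV)")
  if (min_area_cm2 < 0) stop("`min_area_cm2` must be non-negative")
  if (miss_prob < 0 || miss_prob > 1) stop("`miss_prob` must lie in [0, 1]")
  if (blob_rate < 0) stop("`blob_rate` must be non-negative")
  if (kind == "external" && is.null(mask_dir))
    stop("`mask_dir` is required for the external kind")
  structure(
    list(kind = kind, threshold = threshold, min_area_cm2 = min_area_cm2,
         miss_prob = miss_prob, blob_rate = blob_rate, blob_side = blob_side,
         seed = as.integer(seed), mask_dir = mask_dir),
    class = "segmenter_spec"
  )
}

prediction_image <- function(values, template) {
  projection_image((values > 0.5) * 1, template$pixel_spacing, template$angle,
                   provenance = "prediction", frame_dim = template$frame_dim)
}

#' Segment every projection of a MIP stack
#'
#' Produces one binary prediction mask per angle according to a
#' [segmenter_spec()]. The oracle kinds require the matching ground-truth
#' projection stack; the `"noisy_oracle"` kind is bit-reproducible under its
#' seed.
#'
#' @param stack `mip_stack` of SUV projections.
#' @param spec a [segmenter_spec()].
#' @param truth optional `mip_stack` of ground-truth label projections (same
#'   angles and image dimensions); required for `"oracle"`/`"noisy_oracle"`.
#' @return a `mip_stack` of binary predictions (provenance `"prediction"`).
#' @export
segment_stack <- function(stack, spec, truth = NULL) {
  if (!inherits(stack, "mip_stack")) stop("`stack` must be a mip_stack")
  if (!inherits(spec, "segmenter_spec")) stop("`spec` must be a segmenter_spec")
  if (spec$kind %in% c("oracle", "noisy_oracle")) {
    if (is.null(truth))
      stop("`truth` projections are required for the ", spec$kind, " segmenter")
    if (truth$angles$n != stack$angles$n)
      stop("truth and SUV stacks have different angle counts")
    for (i in seq_along(stack$images))
      if (!identical(dim(stack$images[[i]]$values), dim(truth$images[[i]]$values)))
        stop("truth and SUV projection dimensions differ at angle index ", i)
  }
  preds <- switch(
    spec$kind,
    oracle = lapply(truth$images, function(t) prediction_image(t$values, t)),
    threshold = lapply(stack$images, function(im) {
      m <- (im$values >= spec$threshold) * 1
      if (spec$min_area_cm2 > 0 && any(m > 0)) {
        lab <- label_components(m, 8)
        n <- attr(lab, "n")
        px_cm2 <- prod(im$pixel_spacing) / 100
        sizes <- tabulate(lab[lab > 0L], nbins = n) * px_cm2
        fg_idx <- which(lab > 0L)
        m[fg_idx[(sizes < spec$min_area_cm2)[lab[fg_idx]]]] <- 0
      }
      prediction_image(m, im)
    }),
    noisy_oracle = withr::with_seed(spec$seed, {
      lapply(seq_along(truth$images), function(i) {
        t <- truth$images[[i]]
        m <- t$values
        lab <- label_components(m, 8)
        n <- attr(lab, "n")
        if (n > 0) {
          drop <- stats::runif(n) < spec$miss_prob
          if (any(drop)) {
            fg_idx <- which(lab > 0L)
            m[fg_idx[drop[lab[fg_idx]]]] <- 0
          }
        }
        n_blob <- stats::rpois(1, spec$blob_rate)
        if (n_blob > 0) {
          # candidate centers: the body footprint of the SUV projection
          foot <- which(stack$images[[i]]$values > 0, arr.ind = TRUE)
          if (nrow(foot)) {
            pick <- foot[sample.int(nrow(foot), n_blob, replace = TRUE), ,
                         drop = FALSE]
            h <- spec$blob_side %/% 2
            for (bidx in seq_len(n_blob)) {
              r <- max(1, pick[bidx, 1] - h):min(nrow(m), pick[bidx, 1] + h)
              cc <- max(1, pick[bidx, 2] - h):min(ncol(m), pick[bidx, 2] + h)
              m[r, cc] <- 1
            }
          }
        }
        prediction_image(m, t)
      })
    }),
    external = lapply(seq_along(stack$images), function(i) {
      im <- stack$images[[i]]
      m <- read_external_mask(spec$mask_dir, i - 1L, dim(im$values))
      prediction_image(m, im)
    })
  )
  structure(
    list(angles = stack$angles, images = preds, provenance = "prediction",
         frame = stack$frame),
    class = "mip_stack"
  )
}

# external-kind contract: one binary 2D file per angle, named by 0-based
# angle index; PNG (any strictly positive gray is foreground) or 2D NIfTI
read_external_mask <- function(dir, angle_index, expect_dim) {
  stem <- file.path(dir, sprintf("mask_%03d", angle_index))
  cands <- paste0(stem, c(".png", ".nii.gz", ".nii"))
  path <- cands[file.exists(cands)][1]
  if (is.na(path))
    stop("no external mask for angle index ", angle_index, " under ", dir)
  m <- if (grepl("\\.png$", path)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to read PNG masks")
    p <- png::readPNG(path)
    if (length(dim(p)) == 3L) p <- p[, , 1]
    (p > 0) * 1
  } else {
    img <- RNifti::readNifti(path)
    a <- array(as.numeric(img), dim = dim(img))
    if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1]
    (a > 0) * 1
  }
  if (!identical(dim(m), as.integer(expect_dim)) &&
      !identical(dim(m), expect_dim))
    stop("external mask ", basename(path), " has dimensions ",
         paste(dim(m), collapse = "x"), ", stack manifest expects ",
         paste(expect_dim, collapse = "x"))
  m
}
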