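#' Backproject one 2D mask into the reference grid
#'
#' Inverse of the projection step for a single angle: in the theta-rotated
#' frame the 2D mask is replicated along the projection axis (every voxel on a
#' traced ray receives the pixel's value), the volume is rotated back by
#' `-theta` with nearest interpolation so masks stay binary, and the in-plane
#' isotropic resampling and padding applied at projection time are inverted so
#' the output lives on the reference grid.
#'
#' @param mask binary [projection_image()] produced on the case's shared
#'   padded frame.
#' @param theta projection angle in degrees (must match the mask's frame).
#' @param reference reference-grid volume (geometry only is used).
#' @param frame the shared [projection_frame()] of the case.
#' @return a `scalar_volume` of 0/1 shadow values on `reference`'s geometry.
#' @export
backproject_mask <- function(mask, theta, reference, frame = NULL) {
  if (is.null(frame)) frame <- projection_frame(reference)
  side <- frame$side; nz <- frame$iso_dim[3]
  if (!identical(dim(mask$values), c(nz, side)))
    stop("mask dimensions ", paste(dim(mask$values), collapse = "x"),
         " do not match the projection frame (", nz, "x", side, ")")
  # replicate along the projection (y) axis: B[x, y, z] = mask[z, x]
  B <- aperm(array(t(mask$values), c(side, nz, side)), c(1, 3, 2))
  fv <- scalar_volume(B,
                      spacing = c(frame$iso_spacing, frame$iso_spacing,
                                  frame$ref_spacing[3]),
                      origin = reference$origin -
                        frame$pre * c(frame$iso_spacing, frame$iso_spacing,
                                      frame$ref_spacing[3]),
                      axes = frame$axes)
  rv <- rotate_axial(fv, -theta, "nearest")
  unframe_volume(rv, frame, "nearest", reference)
}

#' Reconstruct the raw TPDM by accumulating backprojections
#'
#' Sums [backproject_mask()] over all angles of a prediction stack, in sorted
#' angle order so results are bit-reproducible. Voxels where the 2D shadows of
#' many angles intersect accumulate high counts; the maximum possible value is
#' the number of angles.
#'
#' @param masks `mip_stack` of binary predictions (one per angle).
#' @param reference reference-grid volume (geometry only is used).
#' @return a `raw_tpdm`: a `scalar_volume` of accumulation counts in
#'   `[0, n_angles]` with field `n_angles`.
#' @export
reconstruct_raw <- function(masks, reference) {
  if (!inherits(masks, "mip_stack")) stop("`masks` must be a mip_stack")
  frame <- masks$frame
  ord <- order(masks$angles$angles)
  acc <- array(0, dim(reference$values))
  for (i in ord) {
    bp <- backproject_mask(masks$images[[i]], masks$angles$angles[i],
                           reference, frame)
    acc <- acc + bp$values
  }
  out <- with_values(reference, acc)
  out$n_angles <- masks$angles$n
  class(out) <- c("raw_tpdm", class(out))
  out
}

#' SUV-gated post-processing of the raw TPDM
#'
#' Turns the raw accumulation volume into the final prior: the SUV volume is
#' clipped to the TPDM gate window (default `[0, 5]`, so that most lesion
#' voxels — whose uptake usually exceeds 5 — get similar weighting), the raw
#' TPDM is multiplied voxel-wise by the clipped SUV, the product is normalized
#' by its global maximum (an all-zero product stays zero), and voxels at or
#' below the `percentile_cut`-th percentile of the strictly positive values —
#' mostly streak noise — are set to zero.
#'
#' @param raw a `raw_tpdm` from [reconstruct_raw()].
#' @param suv the *un-normalized* SUV volume on the same geometry.
#' @param config a [preprocess_config()] supplying `tpdm_suv_clip` and
#'   `percentile_cut`.
#' @return a `tpdm`: `scalar_volume` in `[0, 1]` carrying a `provenance` list
#'   (n_angles, percentile cut level and the measured fraction of positive
#'   voxels zeroed by the cut).
#' @export
postprocess <- function(raw, suv, config = preprocess_config()) {
  stopifnot_same_geometry(raw, suv, "raw TPDM and SUV")
  gate <- config$tpdm_suv_clip
  s <- pmin(pmax(suv$values, gate[1]), gate[2])
  p <- raw$values * s
  mx <- max(p)
  if (mx > 0) p <- p / mx
  pos <- p > 0
  n_pos <- sum(pos)
  if (n_pos > 0) {
    cut <- unname(stats::quantile(p[pos], config$percentile_cut / 100, type = 7))
    zeroed <- pos & p <= cut
    p[zeroed] <- 0
    n_zeroed <- sum(zeroed)
  } else {
    cut <- NA_real_
    n_zeroed <- 0L
  }
  out <- with_values(raw, p)
  out$n_angles <- raw$n_angles
  out$provenance <- list(
    n_angles = raw$n_angles,
    percentile_cut = config$percentile_cut,
    tpdm_suv_clip = gate,
    cut_value = cut,
    n_positive = n_pos,
    n_zeroed = n_zeroed,
    fraction_zeroed = if (n_pos > 0) n_zeroed / n_pos else NA_real_
  )
  class(out) <- c("tpdm", "scalar_volume")
  out
}

#' Binarize a TPDM
#'
#' Thresholds the prior at `tau`: `mask = (tpdm > tau)`. The default
#' `tau = 0` selects the full support of the prior.
#'
#' @param tpdm a `tpdm` (or any `scalar_volume` in `[0, 1]`).
#' @param tau threshold in `[0, 1)`.
#' @return a [label_volume()] on the same geometry.
#' @export
binarize_tpdm <- function(tpdm, tau = 0) {
  if (!is.finite(tau) || tau < 0 || tau >= 1)
    stop("`tau` must lie in [0, 1)")
  with_values(tpdm, (tpdm$values > tau) * 1, label = TRUE)
}
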