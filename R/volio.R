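#' Pre-processing configuration
#'
#' Bundles the fixed intensity windows and cropping controls used throughout
#' pre-processing and TPDM post-processing. The defaults are the windows used
#' for whole-body FDG PET/CT work: CT clipped to `[-100, 250]` HU, SUV to
#' `[0, 15]`, MR (water fraction) to `[0, 1000]`, the SUV gate for TPDM
#' post-processing to `[0, 5]`, and removal of the bottom 5th percentile of
#' positive TPDM intensities.
#'
#' @param ct_clip,suv_clip,mr_clip,tpdm_suv_clip length-2 numeric `(lo, hi)`
#'   clip windows, `lo < hi`.
#' @param percentile_cut percentage in (0, 100); TPDM voxels at or below this
#'   percentile of the strictly positive intensities are zeroed.
#' @param crop_margin non-negative integer margin (voxels) added around the
#'   foreground bounding box.
#' @param normalization normalization mode tag; `"fixed-range"` maps the clip
#'   window affinely onto `[0, 1]` (deterministic and comparable across
#'   patients, as opposed to per-volume min-max).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(ct_clip = c(-100, 250),
                              suv_clip = c(0, 15),
                              mr_clip = c(0, 1000),
                              tpdm_suv_clip = c(0, 5),
                              percentile_cut = 5,
                              crop_margin = 2,
                              normalization = "fixed-range") {
  chk <- function(r, nm) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      stop("`", nm, "` must be a finite (lo, hi) pair with lo < hi")
    as.numeric(r)
  }
  if (!is.finite(percentile_cut) || percentile_cut <= 0 || percentile_cut >= 100)
    stop("`percentile_cut` must lie in (0, 100)")
  if (crop_margin < 0) stop("`crop_margin` must be non-negative")
  structure(
    list(
      ct_clip = chk(ct_clip, "ct_clip"),
      suv_clip = chk(suv_clip, "suv_clip"),
      mr_clip = chk(mr_clip, "mr_clip"),
      tpdm_suv_clip = chk(tpdm_suv_clip, "tpdm_suv_clip"),
      percentile_cut = as.numeric(percentile_cut),
      crop_margin = as.integer(crop_margin),
      normalization = normalization
    ),
    class = "preprocess_config"
  )
}

#' Read and write volumes as NIfTI-1
#'
#' `read_volume()` loads a 3D NIfTI-1 image, reorients it to a right-handed
#' convention with the axial (head-foot) axis as the third array axis, and
#' returns a [scalar_volume()] with spacing and origin taken from the header.
#' `write_volume()` stores a volume as double-precision NIfTI-1 so values
#' round-trip exactly (header spacing is float precision, as NIfTI mandates).
#'
#' @param path file path to a `.nii` / `.nii.gz` file.
#' @param label if `TRUE`, validate the image as binary and return a
#'   [label_volume()].
#' @return `read_volume()`: a `scalar_volume` (or `label_volume`);
#'   `write_volume()`: the path, invisibly.
#' @export
read_volume <- function(path, label = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, but header field `dim` declares ",
         length(d), " dimensions")
  try(RNifti::orientation(img) <- "RAS", silent = TRUE)
  sp <- RNifti::pixdim(img)[1:3]
  if (!all(is.finite(sp)) || any(sp <= 0))
    stop("header field `pixdim` has non-finite or non-positive spacing: ",
         paste(signif(sp, 4), collapse = ", "))
  xf <- RNifti::xform(img)
  org <- as.numeric(xf[1:3, 4])
  vals <- array(as.numeric(img), dim = dim(img))
  if (label) label_volume(vals, sp, org) else scalar_volume(vals, sp, org)
}

#' @rdname read_volume
#' @param v volume to write.
#' @export
write_volume <- function(v, path) {
  hdr <- list(
    pixdim = c(1, v$spacing, 0, 0, 0, 0),
    qform_code = 2L,
    quatern_b = 0, quatern_c = 0, quatern_d = 0,
    qoffset_x = v$origin[1], qoffset_y = v$origin[2], qoffset_z = v$origin[3]
  )
  img <- RNifti::asNifti(v$values, reference = hdr, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert a decay-corrected activity volume to SUV
#'
#' Standardized uptake value normalized by body weight:
#' `SUV = activity (Bq/ml) * body weight (g) / injected dose (Bq)`. The
#' activity volume must already be decay-corrected to injection time; that
#' correction is the caller's responsibility (it depends on acquisition
#' metadata this package does not read).
#'
#' @param activity `scalar_volume` of activity concentration in Bq/ml.
#' @param body_weight patient body weight in kg, > 0.
#' @param injected_dose injected tracer dose in Bq, > 0.
#' @return a `scalar_volume` of SUV values on the same geometry.
#' @examples
#' act <- scalar_volume(array(5000, c(2, 2, 2)), spacing = c(2, 2, 2))
#' suv <- to_suv(act, body_weight = 70, injected_dose = 3.5e8)
#' suv$values[1, 1, 1]  # 1.0
#' @export
to_suv <- function(activity, body_weight, injected_dose) {
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("`body_weight` must be positive (kg)")
  if (!is.finite(injected_dose) || injected_dose <= 0)
    stop("`injected_dose` must be positive (Bq)")
  with_values(activity, activity$values * (body_weight * 1000) / injected_dose)
}

# Interpolating gather on a regular grid, in continuous (1-based) voxel index
# coordinates. ci/cj/ck are equal-length vectors; values outside [1, n] per
# axis are filled. Workhorse behind resampling and axial rotation.
grid_sample <- function(values, ci, cj, ck, method = c("linear", "nearest"),
                        fill = 0) {
  method <- match.arg(method)
  d <- dim(values)
  if (method == "nearest") {
    i <- round(ci); j <- round(cj); k <- round(ck)
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    out <- rep(fill, length(ci))
    if (any(ok)) {
      lin <- (i[ok] - 1) + (j[ok] - 1) * d[1] + (k[ok] - 1) * d[1] * d[2] + 1
      out[ok] <- values[lin]
    }
    return(out)
  }
  ok <- ci >= 1 & ci <= d[1] & cj >= 1 & cj <= d[2] & ck >= 1 & ck <= d[3]
  out <- rep(fill, length(ci))
  if (!any(ok)) return(out)
  ci <- ci[ok]; cj <- cj[ok]; ck <- ck[ok]
  i0 <- pmin(floor(ci), d[1] - 1L); i0 <- pmax(i0, 1)
  j0 <- pmin(floor(cj), d[2] - 1L); j0 <- pmax(j0, 1)
  k0 <- pmin(floor(ck), d[3] - 1L); k0 <- pmax(k0, 1)
  # degenerate axes (size 1): clamp offset to the single plane
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  fx <- ci - i0; fy <- cj - j0; fz <- ck - k0
  n1 <- d[1]; n12 <- d[1] * d[2]
  at <- function(i, j, k) values[(i - 1) + (j - 1) * n1 + (k - 1) * n12 + 1]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * at(i0, j0, k0) +
       fx       * (1 - fy) * (1 - fz) * at(i1, j0, k0) +
       (1 - fx) * fy       * (1 - fz) * at(i0, j1, k0) +
       fx       * fy       * (1 - fz) * at(i1, j1, k0) +
       (1 - fx) * (1 - fy) * fz       * at(i0, j0, k1) +
       fx       * (1 - fy) * fz       * at(i1, j0, k1) +
       (1 - fx) * fy       * fz       * at(i0, j1, k1) +
       fx       * fy       * fz       * at(i1, j1, k1)
  out[ok] <- v
  out
}

#' Resample a volume onto a reference grid
#'
#' Interpolates `moving` at the voxel centers of `reference` in physical (mm)
#' coordinates — the step that brings CT or MR onto the PET grid. Regions
#' outside the moving volume's extent receive `fill` (use `-100` for CT so
#' later clipping maps them to the normalized floor; `0` for SUV/MR).
#'
#' @param moving volume to resample.
#' @param reference volume whose grid (dims, spacing, origin) defines the
#'   output; values are ignored.
#' @param interpolation `"linear"` (intensities) or `"nearest"` (labels).
#' @param fill value assigned outside `moving`'s physical extent.
#' @return a volume on `reference`'s geometry.
#' @export
resample_to_reference <- function(moving, reference,
                                  interpolation = c("linear", "nearest"),
                                  fill = 0) {
  interpolation <- match.arg(interpolation)
  if (!identical(moving$axes, reference$axes))
    stop("axes conventions differ between moving and reference volumes")
  d <- dim(reference$values)
  # physical coords of reference voxel centers -> continuous index in moving
  cx <- (reference$origin[1] + (seq_len(d[1]) - 1) * reference$spacing[1] -
           moving$origin[1]) / moving$spacing[1] + 1
  cy <- (reference$origin[2] + (seq_len(d[2]) - 1) * reference$spacing[2] -
           moving$origin[2]) / moving$spacing[2] + 1
  cz <- (reference$origin[3] + (seq_len(d[3]) - 1) * reference$spacing[3] -
           moving$origin[3]) / moving$spacing[3] + 1
  ci <- rep(cx, times = d[2] * d[3])
  cj <- rep(rep(cy, each = d[1]), times = d[3])
  ck <- rep(cz, each = d[1] * d[2])
  vals <- grid_sample(moving$values, ci, cj, ck, interpolation, fill)
  out <- scalar_volume(array(vals, d), reference$spacing, reference$origin,
                       reference$axes)
  if (inherits(moving, "label_volume") && interpolation == "nearest")
    out <- with_values(out, out$values, label = TRUE)
  out
}

#' Foreground cropping
#'
#' Computes the tightest bounding box containing every voxel where the
#' foreground criterion holds in *any* of the supplied volumes (the joint box),
#' expands it by `margin` voxels, clamps it to the grid, and applies the same
#' box to every volume. The default criterion is `value > lower` with
#' `lower = 0` (SUV-style); pass per-volume `lower` values, e.g. `-100` for a
#' clipped CT channel.
#'
#' @param volumes a single volume or a list of volumes on one grid.
#' @param margin margin in voxels (default from [preprocess_config()]).
#' @param lower numeric, recycled over `volumes`: a voxel is foreground when
#'   its value is strictly above this threshold.
#' @return a list with `volumes` (cropped, same order), and `record` — a
#'   `crop_record` holding 1-based inclusive `start`/`stop` indices per axis,
#'   the original dimensions, and an `empty_foreground` flag (when no voxel
#'   meets the criterion the full-grid box is returned with a warning).
#' @seealso [uncrop()]
#' @export
foreground_crop <- function(volumes, margin = 2, lower = 0) {
  single <- inherits(volumes, "scalar_volume")
  if (single) volumes <- list(volumes)
  if (!length(volumes)) stop("no volumes supplied")
  for (v in volumes[-1]) stopifnot_same_geometry(volumes[[1]], v)
  lower <- rep_len(lower, length(volumes))
  d <- dim(volumes[[1]]$values)
  fg <- array(FALSE, d)
  for (i in seq_along(volumes)) fg <- fg | (volumes[[i]]$values > lower[i])
  empty <- !any(fg)
  if (empty) {
    warning("no foreground voxels; returning the full-grid box")
    start <- c(1L, 1L, 1L); stop_ <- d
  } else {
    idx <- which(fg, arr.ind = TRUE)
    start <- unname(pmax(apply(idx, 2, min) - margin, 1L))
    stop_ <- unname(pmin(apply(idx, 2, max) + margin, d))
  }
  record <- structure(
    list(start = as.integer(start), stop = as.integer(stop_),
         original_dim = as.integer(d), empty_foreground = empty),
    class = "crop_record"
  )
  cropped <- lapply(volumes, function(v) {
    vv <- v$values[start[1]:stop_[1], start[2]:stop_[2], start[3]:stop_[3],
                   drop = FALSE]
    out <- with_values(v, vv, label = inherits(v, "label_volume"))
    out$origin <- v$origin + (start - 1) * v$spacing
    out
  })
  if (single) cropped <- cropped[[1]]
  list(volumes = cropped, record = record)
}

#' Undo a foreground crop
#'
#' Restores the original grid dimensions, placing the cropped block back at
#' its recorded position and filling outside with `fill`.
#'
#' @param v cropped volume.
#' @param record the `crop_record` returned by [foreground_crop()].
#' @param fill value outside the recorded box.
#' @return a volume with the original dimensions.
#' @export
uncrop <- function(v, record, fill = 0) {
  d <- record$original_dim
  out <- array(fill, d)
  s <- record$start; e <- record$stop
  out[s[1]:e[1], s[2]:e[2], s[3]:e[3]] <- v$values
  res <- with_values(v, out, label = inherits(v, "label_volume") && fill %in% c(0, 1))
  res$origin <- v$origin - (s - 1) * v$spacing
  res
}

#' Clip and normalize intensities to \[0, 1\]
#'
#' Applies the fixed affine window map `v -> (clamp(v, lo, hi) - lo)/(hi - lo)`.
#' Monotone non-decreasing and idempotent when re-applied with the range
#' `[0, 1]`.
#'
#' @param vol volume (or plain array).
#' @param lo,hi window bounds, `lo < hi`.
#' @return object of the same kind with values in `[0, 1]`.
#' @export
clip_and_normalize <- function(vol, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("need finite window bounds with lo < hi")
  f <- function(x) (pmin(pmax(x, lo), hi) - lo) / (hi - lo)
  if (inherits(vol, "scalar_volume")) with_values(vol, f(vol$values))
  else f(vol)
}

#' Symmetric zero-padding to target dimensions
#'
#' Pads each axis symmetrically with zeros; when the difference is odd the
#' extra voxel goes to the trailing side. The pad record is attached as the
#' `"pad_record"` attribute so [unpad()] can invert exactly.
#'
#' @param vol volume.
#' @param target_dims integer length-3, each `>=` the current dimension.
#' @return the padded volume (attribute `"pad_record"` holds the per-axis
#'   leading pad and original dims).
#' @export
pad_to <- function(vol, target_dims) {
  d <- dim(vol$values)
  target_dims <- as.integer(target_dims)
  if (length(target_dims) != 3L || any(target_dims < d))
    stop("`target_dims` must be length 3 and >= current dimensions")
  pre <- (target_dims - d) %/% 2L
  out <- array(0, target_dims)
  out[pre[1] + seq_len(d[1]), pre[2] + seq_len(d[2]), pre[3] + seq_len(d[3])] <-
    vol$values
  res <- with_values(vol, out, label = inherits(vol, "label_volume"))
  res$origin <- vol$origin - pre * vol$spacing
  attr(res, "pad_record") <- list(pre = pre, original_dim = d)
  res
}

#' @rdname pad_to
#' @param record pad record; defaults to the attribute written by [pad_to()].
#' @export
unpad <- function(vol, record = attr(vol, "pad_record")) {
  if (is.null(record)) stop("no pad record available")
  pre <- record$pre; d <- record$original_dim
  out <- vol$values[pre[1] + seq_len(d[1]), pre[2] + seq_len(d[2]),
                    pre[3] + seq_len(d[3]), drop = FALSE]
  res <- with_values(vol, out, label = inherits(vol, "label_volume"))
  res$origin <- vol$origin + pre * vol$spacing
  attr(res, "pad_record") <- NULL
  res
}
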