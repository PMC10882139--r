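#' Uniform projection angles over \[0, 180)
#'
#' Generates `n` projection angles `k * 180 / n`, `k = 0 .. n-1`, in degrees.
#' Projections from `[180, 360)` are mirror images of these, so the half-open
#' interval suffices; at the standard 5-degree interval this yields the 36
#' predetermined projections used per patient.
#'
#' @param n number of projections, `>= 1`.
#' @return an `angle_set`: list with `angles` (degrees, strictly increasing,
#'   uniform spacing `180/n`), `n`, and the generation rule tag.
#' @examples
#' make_angles(36)$angles[1:4]  # 0 5 10 15
#' @export
make_angles <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  structure(
    list(angles = (seq_len(n) - 1) * 180 / n, n = n, rule = "uniform-half-open"),
    class = "angle_set"
  )
}

#' @export
print.angle_set <- function(x, ...) {
  cat(sprintf("<angle_set> %d angles, spacing %.4g deg: %s%s\n", x$n, 180 / x$n,
              paste(utils::head(x$angles, 6), collapse = ", "),
              if (x$n > 6) ", ..." else ""))
  invisible(x)
}

#' Shared projection frame for a case
#'
#' All projections and backprojections of one case happen on a common
#' rotation-safe frame: the in-plane grid is resampled to isotropic spacing
#' (the minimum of the two in-plane spacings) so rotation does not shear, then
#' zero-padded to a square whose side is the ceiling of the in-plane diagonal,
#' so no intensity leaves the frame at any angle. The axial (z) axis is never
#' touched. The frame records everything needed to invert both steps.
#'
#' @param reference a volume supplying the case geometry.
#' @return a `projection_frame` list: reference geometry, isotropic in-plane
#'   spacing and dims, padded square side `D`, and per-axis leading pads.
#' @export
projection_frame <- function(reference) {
  d <- dim(reference$values)
  sp <- reference$spacing
  iso <- min(sp[1], sp[2])
  needs_resample <- abs(sp[1] - sp[2]) > 1e-9
  iso_dim <- if (needs_resample)
    c(ceiling(d[1] * sp[1] / iso), ceiling(d[2] * sp[2] / iso), d[3])
  else d
  side <- as.integer(ceiling(sqrt(iso_dim[1]^2 + iso_dim[2]^2)))
  pre <- c((side - iso_dim[1]) %/% 2L, (side - iso_dim[2]) %/% 2L, 0L)
  structure(
    list(
      ref_dim = d, ref_spacing = sp, ref_origin = reference$origin,
      axes = reference$axes,
      iso_spacing = iso, iso_dim = as.integer(iso_dim),
      needs_resample = needs_resample,
      side = side, pre = as.integer(pre)
    ),
    class = "projection_frame"
  )
}

# reference-grid volume -> padded isotropic frame volume (side x side x nz)
frame_volume <- function(vol, frame, interpolation) {
  if (frame$needs_resample) {
    tmpl <- scalar_volume(
      array(0, frame$iso_dim),
      spacing = c(frame$iso_spacing, frame$iso_spacing, frame$ref_spacing[3]),
      origin = vol$origin, axes = vol$axes
    )
    vol <- resample_to_reference(vol, tmpl, interpolation)
  }
  pad_to(vol, c(frame$side, frame$side, frame$iso_dim[3]))
}

# padded frame volume -> reference-grid volume (inverse of frame_volume)
unframe_volume <- function(vol, frame, interpolation, reference) {
  rec <- list(pre = frame$pre,
              original_dim = frame$iso_dim)
  v <- unpad(vol, rec)
  if (frame$needs_resample)
    v <- resample_to_reference(v, reference, interpolation)
  v
}

#' Rotate a volume about the axial axis
#'
#' Rotates every axial (z) slice by `theta` degrees about the slice center,
#' counter-clockwise when viewed from +z. Rotation assumes isotropic in-plane
#' spacing (use [projection_frame()] to obtain one); the z axis is untouched.
#' Label volumes should use nearest interpolation to stay binary.
#'
#' @param vol volume with `spacing[1] == spacing[2]`.
#' @param theta rotation angle in degrees.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill value for pixels rotated in from outside the frame.
#' @return the rotated volume on the same grid.
#' @export
rotate_axial <- function(vol, theta, interpolation = c("linear", "nearest"),
                         fill = 0) {
  interpolation <- match.arg(interpolation)
  if (abs(vol$spacing[1] - vol$spacing[2]) > 1e-9)
    stop("in-plane spacing must be isotropic for rotation; ",
         "build a projection_frame first")
  d <- dim(vol$values)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  th <- theta * pi / 180
  co <- cos(th); si <- sin(th)
  i <- rep(seq_len(d[1]), times = d[2]) - cx
  j <- rep(seq_len(d[2]), each = d[1]) - cy
  # inverse mapping: source position = R(-theta) (p - c) + c; the in-plane
  # map is identical for every z-slice, so gather all slices at once
  ci <- co * i + si * j + cx
  cj <- -si * i + co * j + cy
  n12 <- d[1] * d[2]
  Vm <- matrix(vol$values, n12, d[3])
  out_m <- matrix(fill, n12, d[3])
  if (interpolation == "nearest") {
    ii <- round(ci); jj <- round(cj)
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
    lin <- ii[ok] + (jj[ok] - 1) * d[1]
    out_m[ok, ] <- Vm[lin, , drop = FALSE]
  } else {
    ok <- ci >= 1 & ci <= d[1] & cj >= 1 & cj <= d[2]
    cio <- ci[ok]; cjo <- cj[ok]
    i0 <- pmax(pmin(floor(cio), d[1] - 1L), 1)
    j0 <- pmax(pmin(floor(cjo), d[2] - 1L), 1)
    i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2])
    fx <- cio - i0; fy <- cjo - j0
    l00 <- i0 + (j0 - 1) * d[1]; l10 <- i1 + (j0 - 1) * d[1]
    l01 <- i0 + (j1 - 1) * d[1]; l11 <- i1 + (j1 - 1) * d[1]
    out_m[ok, ] <-
      (1 - fx) * (1 - fy) * Vm[l00, , drop = FALSE] +
      fx       * (1 - fy) * Vm[l10, , drop = FALSE] +
      (1 - fx) * fy       * Vm[l01, , drop = FALSE] +
      fx       * fy       * Vm[l11, , drop = FALSE]
  }
  with_values(vol, array(out_m, d),
              label = inherits(vol, "label_volume") &&
                interpolation == "nearest")
}

#' 2D projection image
#'
#' Constructor for the per-angle 2D images produced by [mip()] and
#' [project_label()]. Rows run along the axial (z) index, head to foot;
#' columns along the remaining in-plane axis of the rotated frame.
#'
#' @param values numeric matrix (rows = axial slices, cols = frame side).
#' @param pixel_spacing length-2 `(row, col)` pixel size in mm.
#' @param angle projection angle in degrees.
#' @param provenance `"suv"`, `"ground-truth"` or `"prediction"`.
#' @param frame_dim dimensions of the padded frame the image was formed on.
#' @return a `projection_image` object.
#' @export
projection_image <- function(values, pixel_spacing, angle,
                             provenance = c("suv", "ground-truth", "prediction"),
                             frame_dim = NULL) {
  provenance <- match.arg(provenance)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (provenance != "suv" && !all(values %in% c(0, 1)))
    stop("binary provenance requires values in {0, 1}")
  structure(
    list(values = values, pixel_spacing = as.numeric(pixel_spacing),
         angle = angle, provenance = provenance, frame_dim = frame_dim),
    class = "projection_image"
  )
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %d x %d px, angle %.4g deg, %s\n",
              nrow(x$values), ncol(x$values), x$angle, x$provenance))
  invisible(x)
}

# max over the projection (y) axis of a frame volume; returns z-by-x matrix
.project_max <- function(vals) {
  red <- vals[, 1, , drop = TRUE]
  if (!is.matrix(red)) red <- matrix(red, nrow = dim(vals)[1])
  for (j in seq_len(dim(vals)[2])[-1]) red <- pmax(red, vals[, j, ])
  t(red)
}

#' Maximum intensity projection at one angle
#'
#' Rotates the volume by `theta` about the axial axis on the case's shared
#' padded frame, then takes the maximum along the fixed in-plane projection
#' axis. The result has rows = axial slices and columns = the remaining frame
#' axis, with pixel spacing `(axial spacing, isotropic in-plane spacing)`.
#'
#' @param vol SUV (or other scalar) volume on the reference grid.
#' @param theta projection angle in degrees.
#' @param frame optional shared [projection_frame()]; computed from `vol` if
#'   missing. Pass one frame per case so all angles share dimensions.
#' @param interpolation rotation interpolation (`"linear"` for intensities).
#' @return a [projection_image()] with provenance `"suv"`.
#' @export
mip <- function(vol, theta, frame = NULL,
                interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (is.null(frame)) frame <- projection_frame(vol)
  fv <- frame_volume(vol, frame, interpolation)
  rv <- rotate_axial(fv, theta, interpolation)
  img <- .project_max(rv$values)
  projection_image(img,
                   pixel_spacing = c(frame$ref_spacing[3], frame$iso_spacing),
                   angle = theta, provenance = "suv",
                   frame_dim = dim(fv$values))
}

#' Binary projection of a label volume
#'
#' Same construction as [mip()] with nearest-interpolation rotation and a
#' logical-OR (max) along the projection axis; the output stays binary.
#'
#' @param label a [label_volume()].
#' @inheritParams mip
#' @return a binary [projection_image()] with provenance `"ground-truth"`.
#' @export
project_label <- function(label, theta, frame = NULL) {
  if (is.null(frame)) frame <- projection_frame(label)
  fv <- frame_volume(label, frame, "nearest")
  rv <- rotate_axial(fv, theta, "nearest")
  img <- .project_max(rv$values)
  projection_image((img > 0.5) * 1,
                   pixel_spacing = c(frame$ref_spacing[3], frame$iso_spacing),
                   angle = theta, provenance = "ground-truth",
                   frame_dim = dim(fv$values))
}

#' Multi-directional projection stack
#'
#' Applies [mip()] (scalar volumes) or [project_label()] (label volumes) at
#' every angle of an [make_angles()] set, on one shared padded frame so all
#' images have identical dimensions.
#'
#' @param vol volume to project.
#' @param angles an `angle_set`.
#' @param frame optional shared frame; computed from `vol` if missing.
#' @return a `mip_stack`: list with `angles`, `images` (one
#'   [projection_image()] per angle), `provenance`, and the `frame`.
#' @export
mip_stack <- function(vol, angles, frame = NULL) {
  if (!inherits(angles, "angle_set")) stop("`angles` must be an angle_set")
  if (is.null(frame)) frame <- projection_frame(vol)
  is_label <- inherits(vol, "label_volume")
  images <- lapply(angles$angles, function(th) {
    if (is_label) project_label(vol, th, frame) else mip(vol, th, frame)
  })
  structure(
    list(angles = angles, images = images,
         provenance = if (is_label) "ground-truth" else "suv",
         frame = frame),
    class = "mip_stack"
  )
}

#' @export
print.mip_stack <- function(x, ...) {
  d <- dim(x$images[[1]]$values)
  cat(sprintf("<mip_stack> %d projections (%s), %d x %d px each\n",
              x$angles$n, x$provenance, d[1], d[2]))
  invisible(x)
}
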