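#' 3D scalar volume with voxel geometry
#'
#' The basic container of the package: a 3D numeric grid together with its
#' voxel spacing (mm), origin (mm) and an axes tag fixing the third array axis
#' as the axial (head-to-foot, z) direction. SUV, CT, MR and TPDM volumes are
#' all `scalar_volume` objects; binary masks are [label_volume()] objects with
#' identical geometry.
#'
#' @param values numeric 3D array, indexed `[x, y, z]` with z the axial axis.
#' @param spacing numeric length-3, voxel edge lengths `(sx, sy, sz)` in mm;
#'   all strictly positive.
#' @param origin numeric length-3, physical position (mm) of voxel `(1, 1, 1)`.
#' @param axes axis-convention tag; all volumes combined in any operation must
#'   carry the same tag. Default `"axial-z"`.
#' @return an object of class `scalar_volume`.
#' @examples
#' v <- scalar_volume(array(0, c(4, 4, 4)), spacing = c(2.04, 2.04, 3))
#' dim(v$values)
#' @export
scalar_volume <- function(values, spacing, origin = c(0, 0, 0), axes = "axial-z") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array (got ", length(dim(values)), " dims)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(
    list(values = values, spacing = spacing, origin = origin, axes = axes),
    class = "scalar_volume"
  )
}

#' Binary 3D label volume
#'
#' A mask on the same geometry as a [scalar_volume()]; values are restricted
#' to 0/1. Used for ground-truth tumor annotations and binarized predictions.
#'
#' @inheritParams scalar_volume
#' @param values 3D array containing only 0 and 1 (logical arrays are coerced).
#' @return an object of class `c("label_volume", "scalar_volume")`.
#' @export
label_volume <- function(values, spacing, origin = c(0, 0, 0), axes = "axial-z") {
  if (is.logical(values)) {
    d <- dim(values)
    values <- array(as.numeric(values), d)
  }
  if (!all(values %in% c(0, 1)))
    stop("label volumes may contain only 0 and 1")
  v <- scalar_volume(values, spacing, origin, axes)
  class(v) <- c("label_volume", "scalar_volume")
  v
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<%s> %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm, axes %s\n",
    class(x)[1], d[1], d[2], d[3],
    x$spacing[1], x$spacing[2], x$spacing[3], x$axes
  ))
  rng <- range(x$values)
  cat(sprintf("  value range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Volume geometry helpers
#'
#' `vol_dim()` returns grid dimensions; `same_geometry()` tests that two
#' volumes share dimensions, spacing, origin and axes convention (within
#' floating-point tolerance on the continuous fields).
#'
#' @param v,a,b volumes.
#' @param tol numeric tolerance on spacing/origin comparison.
#' @return `vol_dim()`: integer length-3; `same_geometry()`: logical scalar.
#' @export
vol_dim <- function(v) dim(v$values)

#' @rdname vol_dim
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol) &&
    identical(a$axes, b$axes)
}

stopifnot_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    stop(what, " must share grid dimensions, spacing, origin and axes convention")
  invisible(TRUE)
}

# new volume carrying the geometry of `ref` but fresh values
with_values <- function(ref, values, label = FALSE) {
  if (label) label_volume(values, ref$spacing, ref$origin, ref$axes)
  else scalar_volume(values, ref$spacing, ref$origin, ref$axes)
}

#' Voxel volume in ml
#'
#' @param v a volume (only its spacing is used).
#' @return volume of one voxel in ml (1 ml = 1000 mm^3).
#' @export
voxel_volume_ml <- function(v) prod(v$spacing) / 1000
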