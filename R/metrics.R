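# -- input coercion helpers ---------------------------------------------------

as_mask_array <- function(x) {
  if (inherits(x, "scalar_volume")) return(x$values)
  if (inherits(x, "projection_image")) return(x$values)
  if (is.array(x) || is.matrix(x)) return(x)
  stop("cannot interpret input of class ", class(x)[1], " as a mask")
}

mask_spacing <- function(x, spacing) {
  if (!is.null(spacing)) return(as.numeric(spacing))
  if (inherits(x, "scalar_volume")) return(x$spacing)
  if (inherits(x, "projection_image")) return(x$pixel_spacing)
  stop("`spacing` must be supplied for plain arrays")
}

check_binary <- function(m) {
  if (!all(m %in% c(0, 1))) stop("mask must be binary (0/1)")
  invisible(m)
}

# -- connected components (2D / 3D, configurable connectivity) ----------------

conn_offsets <- function(nd, connectivity) {
  if (nd == 2L) {
    if (!connectivity %in% c(4, 8)) stop("2D connectivity must be 4 or 8")
    g <- expand.grid(dx = -1:1, dy = -1:1)
    g <- g[!(g$dx == 0 & g$dy == 0), ]
    if (connectivity == 4) g <- g[abs(g$dx) + abs(g$dy) == 1, ]
    return(as.matrix(g))
  }
  if (!connectivity %in% c(6, 18, 26)) stop("3D connectivity must be 6, 18 or 26")
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  s <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  g <- g[s > 0, ]; s <- s[s > 0]
  if (connectivity == 6) g <- g[s == 1, ]
  if (connectivity == 18) g <- g[s <= 2, ]  # faces + edges, corners excluded
  as.matrix(g)
}

#' Label connected components of a binary mask
#'
#' Deterministic connected-component labeling for 2D matrices (4- or
#' 8-connectivity) and 3D arrays (6-, 18- or 26-connectivity). 18-connectivity
#' — face plus edge neighbors, corners excluded — is the convention used for
#' lesion-wise metrics in 3D. Components are numbered in order of their
#' smallest linear index, so labeling is reproducible.
#'
#' Implemented as vectorized minimum-label propagation with pointer-jumping
#' path compression (no compiled code, no external dependency).
#'
#' @param mask binary matrix or 3D array (or a [label_volume()]).
#' @param connectivity neighborhood size; defaults to 8 in 2D and 18 in 3D.
#' @return integer array of the same shape: 0 for background, 1..K component
#'   labels; attribute `"n"` holds K.
#' @export
label_components <- function(mask, connectivity = NULL) {
  m <- as_mask_array(mask)
  check_binary(m)
  d <- dim(m)
  nd <- length(d)
  if (is.null(connectivity)) connectivity <- if (nd == 2L) 8 else 18
  off <- conn_offsets(nd, connectivity)
  fg <- which(m > 0)
  lab_arr <- array(0L, d)
  if (!length(fg)) { attr(lab_arr, "n") <- 0L; return(lab_arr) }
  nfg <- length(fg)
  id <- integer(prod(d)); id[fg] <- seq_len(nfg)
  coords <- arrayInd(fg, d)
  strides <- cumprod(c(1, d[-nd]))
  # neighbor fg-id matrix, 0 where absent
  nb <- matrix(0L, nfg, nrow(off))
  for (mcol in seq_len(nrow(off))) {
    o <- off[mcol, ]
    ok <- rep(TRUE, nfg)
    for (ax in seq_len(nd)) {
      cc <- coords[, ax] + o[ax]
      ok <- ok & cc >= 1L & cc <= d[ax]
    }
    lin <- fg[ok] + as.integer(sum(o * strides))
    nb[ok, mcol] <- id[lin]
  }
  lab <- seq_len(nfg)
  repeat {
    old <- lab
    nl <- lab
    for (mcol in seq_len(ncol(nb))) {
      idx <- nb[, mcol]
      ok <- idx > 0L
      if (any(ok)) nl[ok] <- pmin(nl[ok], lab[idx[ok]])
    }
    lab <- pmin(lab, nl)
    lab <- lab[lab]; lab <- lab[lab]  # path compression
    if (identical(lab, old)) break
  }
  roots <- sort(unique(lab))
  lab_arr[fg] <- match(lab, roots)
  attr(lab_arr, "n") <- length(roots)
  lab_arr
}

#' 3D lesion components with volume filter
#'
#' Labels a binary 3D mask with 18-connectivity and discards components whose
#' volume is at or below `min_volume_ml` (the standard lesion-wise convention
#' keeps components with volume > 0.5 ml). Set `min_volume_ml = 0` to keep
#' everything.
#'
#' @param mask binary 3D array or [label_volume()].
#' @param spacing voxel spacing in mm (taken from the volume if omitted).
#' @param min_volume_ml retain components with volume strictly above this (ml).
#' @param connectivity 3D connectivity (default 18).
#' @return a `lesion_components` object: integer `labels` array (retained
#'   components renumbered 1..K), and a tibble `components` with per-component
#'   voxel counts and volumes in ml.
#' @export
components3d <- function(mask, spacing = NULL, min_volume_ml = 0.5,
                         connectivity = 18) {
  sp <- mask_spacing(mask, spacing)
  m <- as_mask_array(mask)
  if (length(dim(m)) != 3L) stop("`mask` must be 3D")
  lab <- label_components(m, connectivity)
  n <- attr(lab, "n")
  vox_ml <- prod(sp) / 1000
  if (n == 0L) {
    tbl <- tibble::tibble(component = integer(), voxels = integer(),
                          volume_ml = numeric())
  } else {
    cnt <- tabulate(lab[lab > 0L], nbins = n)
    tbl <- tibble::tibble(component = seq_len(n), voxels = cnt,
                          volume_ml = cnt * vox_ml)
    keep <- tbl$volume_ml > min_volume_ml
    if (!all(keep)) {
      relab <- integer(n)
      relab[which(keep)] <- seq_len(sum(keep))
      lab[lab > 0L] <- relab[lab[lab > 0L]]
      tbl <- tbl[keep, ]
      tbl$component <- seq_len(nrow(tbl))
    }
  }
  structure(
    list(labels = lab, components = tbl, connectivity = connectivity,
         min_volume_ml = min_volume_ml, spacing = sp),
    class = "lesion_components"
  )
}

#' @export
print.lesion_components <- function(x, ...) {
  cat(sprintf("<lesion_components> %d component(s), %d-connectivity, filter > %.3g ml\n",
              nrow(x$components), x$connectivity, x$min_volume_ml))
  if (nrow(x$components)) print(x$components)
  invisible(x)
}

# -- overlap metrics ----------------------------------------------------------

#' Dice overlap coefficient
#'
#' `2 |P ∩ G| / (|P| + |G|)` between two binary masks of identical geometry.
#' When both masks are empty the score is 1 and the result carries the
#' attribute `both_empty = TRUE` so aggregation code can treat the case
#' explicitly.
#'
#' @param pred,gt binary masks (arrays, volumes or projection images) of the
#'   same dimensions.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(pred, gt) {
  p <- as_mask_array(pred); g <- as_mask_array(gt)
  if (!identical(dim(p), dim(g))) stop("mask dimensions differ")
  check_binary(p); check_binary(g)
  np <- sum(p); ng <- sum(g)
  if (np + ng == 0) return(structure(1, both_empty = TRUE))
  2 * sum(p * g) / (np + ng)
}

#' False-negative and false-positive area of a 2D prediction
#'
#' FNA is the mean area (cm^2) of 8-connected ground-truth components with no
#' overlapping predicted pixel — i.e. the average size of completely missed 2D
#' lesions; FPA is the symmetric quantity for predicted components with no
#' ground-truth overlap. Either is 0 when no such component exists.
#'
#' @param pred2d,gt2d binary 2D masks ([projection_image()] or matrix).
#' @param pixel_spacing length-2 pixel size (mm); taken from a projection
#'   image if omitted.
#' @return named numeric `c(fna = ..., fpa = ...)` in cm^2.
#' @export
fna_fpa <- function(pred2d, gt2d, pixel_spacing = NULL) {
  sp <- mask_spacing(pred2d, pixel_spacing)
  p <- as_mask_array(pred2d); g <- as_mask_array(gt2d)
  if (!identical(dim(p), dim(g))) stop("mask dimensions differ")
  check_binary(p); check_binary(g)
  px_cm2 <- prod(sp) / 100  # mm^2 -> cm^2
  missed_area <- function(ref, other) {
    lab <- label_components(ref, 8)
    n <- attr(lab, "n")
    if (n == 0L) return(0)
    hit <- tabulate(lab[other > 0 & lab > 0L], nbins = n) > 0
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    if (all(hit)) 0 else mean(sizes[!hit]) * px_cm2
  }
  c(fna = missed_area(g, p), fpa = missed_area(p, g))
}

#' Lesion-wise detection counts
#'
#' Applies [components3d()] (18-connectivity, > `min_volume_ml` filter) to both
#' masks. A ground-truth component counts as detected (TP) when it overlaps at
#' least one predicted foreground voxel (the raw prediction, not its filtered
#' components); otherwise it is an FN. A predicted component overlapping no
#' ground-truth foreground voxel is an FP.
#'
#' @param pred,gt binary 3D masks on one geometry.
#' @param spacing voxel spacing in mm (taken from volumes if omitted).
#' @param min_volume_ml component volume filter (ml), default 0.5.
#' @param filter apply the volume filter to `"both"` masks (default) or to the
#'   `"prediction"` only.
#' @return a tibble with columns `tp`, `fn`, `fp`, `sensitivity`, `precision`
#'   (rates are `NA` when undefined: no ground-truth lesions, or no predicted
#'   components).
#' @export
lesion_counts <- function(pred, gt, spacing = NULL, min_volume_ml = 0.5,
                          filter = c("both", "prediction")) {
  filter <- match.arg(filter)
  sp <- mask_spacing(pred, spacing)
  p <- as_mask_array(pred); g <- as_mask_array(gt)
  if (!identical(dim(p), dim(g))) stop("mask geometries differ")
  gt_min <- if (filter == "both") min_volume_ml else 0
  gcomp <- components3d(g, sp, min_volume_ml = gt_min)
  pcomp <- components3d(p, sp, min_volume_ml = min_volume_ml)
  ng <- nrow(gcomp$components); np <- nrow(pcomp$components)
  g_hit <- if (ng) tabulate(gcomp$labels[p > 0 & gcomp$labels > 0L],
                            nbins = ng) > 0 else logical()
  p_hit <- if (np) tabulate(pcomp$labels[g > 0 & pcomp$labels > 0L],
                            nbins = np) > 0 else logical()
  tp <- sum(g_hit); fn <- ng - tp; fp <- sum(!p_hit)
  tibble::tibble(
    tp = tp, fn = fn, fp = fp,
    sensitivity = if (ng > 0) tp / ng else NA_real_,
    precision = if (np > 0) sum(p_hit) / np else NA_real_
  )
}

# boundary voxels: foreground with a background (or out-of-grid) face neighbor
mask_boundary <- function(m) {
  d <- dim(m)
  fg <- m > 0
  interior <- fg
  shift_ok <- function(ax, by) {
    out <- array(FALSE, d)
    n <- d[ax]
    idx_src <- if (by > 0) 1:(n - 1) else 2:n
    idx_dst <- if (by > 0) 2:n else 1:(n - 1)
    if (length(d) == 2L) {
      if (ax == 1) out[idx_dst, ] <- fg[idx_src, ] else out[, idx_dst] <- fg[, idx_src]
    } else {
      if (ax == 1) out[idx_dst, , ] <- fg[idx_src, , ]
      else if (ax == 2) out[, idx_dst, ] <- fg[, idx_src, ]
      else out[, , idx_dst] <- fg[, , idx_src]
    }
    out
  }
  for (ax in seq_along(d)) {
    interior <- interior & shift_ok(ax, 1) & shift_ok(ax, -1)
  }
  fg & !interior
}

# for each row of A (n x k), min Euclidean distance to rows of B; chunked
min_cross_dist <- function(A, B, chunk = 256L) {
  n <- nrow(A)
  out <- numeric(n)
  B2 <- rowSums(B^2)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    Ai <- A[i:j, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), B2, "+") - 2 * Ai %*% t(B)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
    i <- j + 1L
  }
  out
}

#' 95th-percentile Hausdorff distance (HD95)
#'
#' Robust surface distance between two binary masks: directed
#' boundary-to-boundary distances are computed in both directions in physical
#' mm, pooled, and the 95th percentile (linear interpolation) is returned.
#' Boundary voxels are foreground voxels with a background face (6-)neighbor,
#' grid edges counting as background. Symmetric by construction.
#'
#' @param a,b binary masks on one geometry.
#' @param spacing voxel spacing in mm (taken from volumes if omitted).
#' @param percentile percentile of the pooled distances (default 95).
#' @return distance in mm, or `NA` (with a warning) when either mask is empty
#'   — never a silent 0.
#' @export
hd95 <- function(a, b, spacing = NULL, percentile = 95) {
  sp <- mask_spacing(a, spacing)
  A <- as_mask_array(a); B <- as_mask_array(b)
  if (!identical(dim(A), dim(B))) stop("mask geometries differ")
  check_binary(A); check_binary(B)
  if (sum(A) == 0 || sum(B) == 0) {
    warning("HD95 undefined for an empty mask")
    return(NA_real_)
  }
  nd <- length(dim(A))
  pa <- sweep(which(mask_boundary(A), arr.ind = TRUE), 2, sp[seq_len(nd)], "*")
  pb <- sweep(which(mask_boundary(B), arr.ind = TRUE), 2, sp[seq_len(nd)], "*")
  d_ab <- min_cross_dist(pa, pb)
  d_ba <- min_cross_dist(pb, pa)
  unname(stats::quantile(c(d_ab, d_ba), percentile / 100, type = 7))
}

#' Metabolic tumor volume (ml) and SUVmax
#'
#' `mtv()` is the foreground voxel count times the voxel volume, in ml;
#' `suvmax()` is the maximum SUV over the mask's foreground (`NA` for an empty
#' mask — undefined, never 0).
#'
#' @param mask binary mask (array or [label_volume()]).
#' @param spacing voxel spacing in mm (taken from the volume if omitted).
#' @return `mtv()`: volume in ml.
#' @export
mtv <- function(mask, spacing = NULL) {
  sp <- mask_spacing(mask, spacing)
  m <- as_mask_array(mask)
  check_binary(m)
  sum(m) * prod(sp) / 1000
}

#' @rdname mtv
#' @param suv SUV volume sharing the mask's geometry.
#' @export
suvmax <- function(suv, mask) {
  s <- if (inherits(suv, "scalar_volume")) suv$values else suv
  m <- as_mask_array(mask)
  if (!identical(dim(s), dim(m))) stop("SUV and mask geometries differ")
  if (sum(m) == 0) return(NA_real_)
  max(s[m > 0])
}

#' Pearson correlation coefficient
#'
#' Standard Pearson correlation between two equal-length vectors, as used for
#' patient-wise MTV of prediction vs ground truth. Returns `NA` when either
#' vector has fewer than 3 values or zero variance.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in `[-1, 1]`, or `NA` when degenerate.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the paired differences `a - b`. Zero
#' differences are dropped (classic treatment). For effective sample size
#' `n <= exact_max` the p-value is computed by exhaustive enumeration of all
#' `2^n` sign assignments of the (tie-averaged) ranks, which is correct in the
#' presence of ties; above that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exact_max largest effective n for the exact branch (default 12).
#' @return list with `p_value`, statistic `V` (sum of positive-difference
#'   ranks), effective `n`, and `method`. `p_value` is `NA` when all
#'   differences are zero.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 12) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p_value = NA_real_, V = NA_real_, n = 0L, method = "undefined"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of V over all 2^n sign assignments
    sums <- 0
    for (ri in r) sums <- as.vector(outer(sums, c(0, ri), "+"))
    p_le <- mean(sums <= V + 1e-9)
    p_ge <- mean(sums >= V - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(p_value = p, V = V, n = n, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
  list(p_value = min(1, 2 * stats::pnorm(-abs(z))), V = V, n = n,
       method = "normal-approximation")
}
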