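#' Synthetic whole-body phantom specification
#'
#' Describes a synthetic case: a body ellipsoid filled with soft-tissue
#' background uptake, ellipsoidal tumor lesions with a smooth cosine-tapered
#' uptake profile, high-uptake physiological hot spots (brain/bladder-like)
#' that are *excluded* from the ground truth, and optional additive Gaussian
#' noise. Defaults mirror a whole-body FDG examination digitized at the common
#' (2.04, 2.04, 3.00) mm PET voxel size.
#'
#' @param dims integer length-3 grid dimensions.
#' @param spacing voxel spacing (mm).
#' @param body list with `center` (mm) and `radii` (mm) of the body ellipsoid;
#'   defaults to an ellipsoid filling ~90% of the grid.
#' @param lesions list of lesions, each a list with `center` (mm), `radii`
#'   (mm, length 3), `peak_suv` (> background).
#' @param hot_spots list of physiological hot spots, each with `center`,
#'   `radius` (mm) and `suv`; never part of the ground truth.
#' @param background_suv soft-tissue background uptake inside the body.
#' @param noise list with `kind` (`"gaussian"` or `"none"`) and `sd`.
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(dims = c(64, 64, 64),
                         spacing = c(2.04, 2.04, 3.00),
                         body = NULL,
                         lesions = list(),
                         hot_spots = list(),
                         background_suv = 1.0,
                         noise = list(kind = "gaussian", sd = 0.1),
                         seed = 1L) {
  dims <- as.integer(dims); spacing <- as.numeric(spacing)
  if (length(dims) != 3L || any(dims < 1L)) stop("`dims` must be 3 positive integers")
  if (length(spacing) != 3L || any(spacing <= 0)) stop("`spacing` must be positive (mm)")
  extent <- dims * spacing
  if (is.null(body))
    body <- list(center = extent / 2, radii = extent * 0.45)
  for (l in lesions) {
    if (any(l$radii <= 0)) stop("lesion radii must be positive")
    if (l$peak_suv <= background_suv)
      stop("lesion peak SUV must exceed the background level")
  }
  spec <- structure(
    list(dims = dims, spacing = spacing, body = body, lesions = lesions,
         hot_spots = hot_spots, background_suv = background_suv,
         noise = noise, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  check_no_overlap(spec)
  spec
}

# conservative bounding-sphere overlap test keeps the truth table unambiguous
check_no_overlap <- function(spec) {
  objs <- c(
    lapply(spec$lesions, function(l) list(center = l$center, r = max(l$radii))),
    lapply(spec$hot_spots, function(h) list(center = h$center, r = h$radius))
  )
  if (length(objs) < 2) return(invisible(TRUE))
  for (i in seq_len(length(objs) - 1)) for (j in (i + 1):length(objs)) {
    d <- sqrt(sum((objs[[i]]$center - objs[[j]]$center)^2))
    if (d < objs[[i]]$r + objs[[j]]$r)
      stop("lesion/hot-spot declarations ", i, " and ", j,
           " overlap (bounding spheres); rejected to keep the truth table unambiguous")
  }
  invisible(TRUE)
}

# normalized ellipsoid radius rho at every voxel center (arrays recycled)
.rho <- function(X, Y, Z, center, radii) {
  sqrt(((X - center[1]) / radii[1])^2 +
       ((Y - center[2]) / radii[2])^2 +
       ((Z - center[3]) / radii[3])^2)
}

#' Generate a synthetic phantom case
#'
#' Builds the SUV volume (background + lesions + hot spots + seeded noise),
#' a smooth anatomical body-density channel, the ground-truth label (the
#' union of voxelized lesion ellipsoids only — hot spots are deliberately
#' excluded so they act as false-positive stressors), and a per-lesion truth
#' table of MTV and SUVmax.
#'
#' Lesion uptake follows `background + (peak - background) * cos(pi/2 * rho)`
#' with `rho` the normalized ellipsoid radius, so the peak sits at the lesion
#' center and the profile tapers smoothly to background at the boundary.
#'
#' @param spec a [phantom_spec()].
#' @return list with `suv`, `anat` (`scalar_volume`s), `gt` ([label_volume()])
#'   and `truth` (tibble: lesion, mtv_ml, suvmax, the declared peak).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  d <- spec$dims; sp <- spec$spacing
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  z <- (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  rho_body <- .rho(X, Y, Z, spec$body$center, spec$body$radii)
  body <- rho_body <= 1
  suv <- array(0, d)
  suv[body] <- spec$background_suv
  gt <- array(0, d)
  truth <- vector("list", length(spec$lesions))
  vox_ml <- prod(sp) / 1000
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    rho <- .rho(X, Y, Z, l$center, l$radii)
    inside <- rho <= 1
    suv[inside] <- spec$background_suv +
      (l$peak_suv - spec$background_suv) * cos(pi / 2 * rho[inside])
    # sample the declared peak exactly at the lesion's center voxel, so the
    # truth-table SUVmax is realized on the grid
    cidx <- pmin(pmax(round(l$center / sp) + 1, 1), d)
    suv[cidx[1], cidx[2], cidx[3]] <- l$peak_suv
    gt[inside] <- 1
    truth[[i]] <- tibble::tibble(
      lesion = i, mtv_ml = sum(inside) * vox_ml, suvmax = l$peak_suv
    )
  }
  for (h in spec$hot_spots) {
    rho <- .rho(X, Y, Z, h$center, rep(h$radius, 3))
    inside <- rho <= 1
    suv[inside] <- spec$background_suv +
      (h$suv - spec$background_suv) * cos(pi / 2 * rho[inside])
    cidx <- pmin(pmax(round(h$center / sp) + 1, 1), d)
    suv[cidx[1], cidx[2], cidx[3]] <- h$suv
  }
  if (identical(spec$noise$kind, "gaussian") && spec$noise$sd > 0) {
    suv <- withr::with_seed(spec$seed, {
      n <- array(stats::rnorm(prod(d), 0, spec$noise$sd), d)
      out <- suv
      out[body] <- pmax(out[body] + n[body], 0)  # SUV cannot be negative
      out
    })
  }
  anat <- array(0, d)
  anat[body] <- 1 - 0.5 * rho_body[body]^2  # smooth density, 1 at core
  list(
    suv = scalar_volume(suv, sp),
    anat = scalar_volume(anat, sp),
    gt = label_volume(gt, sp),
    truth = if (length(truth)) do.call(rbind, truth)
            else tibble::tibble(lesion = integer(), mtv_ml = numeric(),
                                suvmax = numeric())
  )
}

#' Sample a reproducible phantom cohort
#'
#' Draws `n_cases` phantom specifications with per-case lesion counts, sizes
#' and peak uptake values from declared distributions. Defaults reflect a
#' lymphoma-like whole-body cohort: lesion count ~ round N(7, 2) clamped to
#' at least 1, peak SUV ~ N(8.88, 4.84) truncated below at 2, and a
#' configurable fraction of "small" lesions with MTV under 2 ml (the regime
#' where a segmentation prior matters most); the remaining lesions draw radii
#' giving MTVs up to tens of ml. Lesions are spheres by default so analytic
#' volumes are available; hot spots sit at the body's extremes (brain-like
#' top, bladder-like lower torso).
#'
#' @param n_cases number of cases (0 gives an empty list).
#' @param dims,spacing grid geometry per case.
#' @param n_lesions_mean,n_lesions_sd lesion-count distribution.
#' @param suv_mean,suv_sd,suv_min peak-SUV distribution (truncated normal).
#' @param small_fraction probability that a lesion is "small" (< 2 ml).
#' @param hot_spots include the two default physiological hot spots.
#' @param noise_sd Gaussian noise standard deviation (SUV units).
#' @param background_suv soft-tissue background uptake.
#' @param seed cohort seed; case i uses `seed + i` so cases are independent
#'   and the whole cohort is reproducible.
#' @param max_tries rejection-sampling attempts per lesion placement.
#' @return list of [phantom_spec()] objects.
#' @export
sample_cohort <- function(n_cases,
                          dims = c(64, 64, 64), spacing = c(2.04, 2.04, 3.00),
                          n_lesions_mean = 7, n_lesions_sd = 2,
                          suv_mean = 8.88, suv_sd = 4.84, suv_min = 2,
                          small_fraction = 0.4,
                          hot_spots = TRUE,
                          noise_sd = 0.1,
                          background_suv = 1.0,
                          seed = 1L, max_tries = 200L) {
  n_cases <- as.integer(n_cases)
  if (n_cases < 0L) stop("`n_cases` must be non-negative")
  if (small_fraction < 0 || small_fraction > 1)
    stop("`small_fraction` must lie in [0, 1]")
  if (n_cases == 0L) return(list())
  extent <- dims * spacing
  lapply(seq_len(n_cases), function(i) {
    withr::with_seed(as.integer(seed) + i, {
      n_les <- max(1L, as.integer(round(stats::rnorm(1, n_lesions_mean,
                                                     n_lesions_sd))))
      body_c <- extent / 2
      body_r <- extent * 0.45
      hs <- if (hot_spots) list(
        list(center = c(body_c[1], body_c[2], body_c[3] + 0.78 * body_r[3]),
             radius = 0.10 * min(extent), suv = 8),
        list(center = c(body_c[1], body_c[2], body_c[3] - 0.55 * body_r[3]),
             radius = 0.08 * min(extent), suv = 10)
      ) else list()
      placed <- list()
      for (k in seq_len(n_les)) {
        small <- stats::runif(1) < small_fraction
        # radius from target MTV: small < 2 ml, large ~ 2-40 ml
        vol_ml <- if (small) stats::runif(1, 0.3, 2)
                  else exp(stats::runif(1, log(2), log(40)))
        r <- (vol_ml * 1000 * 3 / (4 * pi))^(1 / 3)
        peak <- max(suv_min, stats::rnorm(1, suv_mean, suv_sd))
        ok <- FALSE
        for (t in seq_len(max_tries)) {
          u <- stats::runif(3, -0.75, 0.75)
          ctr <- body_c + u * body_r
          if (.rho(ctr[1], ctr[2], ctr[3], body_c, body_r - r) > 1) next
          cand <- list(center = ctr, radii = rep(r, 3), peak_suv = peak)
          clash <- any(vapply(c(placed, hs), function(o) {
            orad <- if (!is.null(o$radius)) o$radius else max(o$radii)
            sqrt(sum((o$center - ctr)^2)) < orad + r + min(spacing)
          }, logical(1)))
          if (!clash) { placed[[length(placed) + 1]] <- cand; ok <- TRUE; break }
        }
        if (!ok) next  # drop unplaceable lesion rather than fail the cohort
      }
      phantom_spec(
        dims = dims, spacing = spacing,
        body = list(center = body_c, radii = body_r),
        lesions = placed, hot_spots = hs,
        background_suv = background_suv,
        noise = list(kind = if (noise_sd > 0) "gaussian" else "none",
                     sd = noise_sd),
        seed = as.integer(seed) + i
      )
    })
  })
}
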