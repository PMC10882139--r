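#' End-to-end pipeline configuration
#'
#' @param n_angles number of predetermined projections (default 36, i.e. a
#'   5-degree interval over `[0, 180)`).
#' @param segmenter a [segmenter_spec()] driving the 2D stage.
#' @param preprocess a [preprocess_config()].
#' @param patch_size sliding-window patch dimensions for the downstream 3D
#'   segmenter (default `c(160, 160, 160)`).
#' @param patch_overlap overlap fraction between consecutive patches in
#'   `[0, 1)` (default 0.25).
#' @param tau binarization threshold used when the pipeline needs a binary
#'   TPDM (default 0, the full support).
#' @param seed master seed.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(n_angles = 36,
                            segmenter = segmenter_spec("oracle"),
                            preprocess = preprocess_config(),
                            patch_size = c(160, 160, 160),
                            patch_overlap = 0.25,
                            tau = 0,
                            seed = 1L) {
  if (patch_overlap < 0 || patch_overlap >= 1)
    stop("`patch_overlap` must lie in [0, 1)")
  structure(
    list(n_angles = as.integer(n_angles), segmenter = segmenter,
         preprocess = preprocess, patch_size = as.integer(patch_size),
         patch_overlap = patch_overlap, tau = tau, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full TPDM pipeline on one case
#'
#' Stage 1: multi-directional MIPs of the SUV volume (plus ground-truth
#' projections when a label is supplied) and 2D segmentation per the
#' configured segmenter. Stage 2: backprojection reconstruction of the raw
#' TPDM and SUV-gated post-processing. Stage 3 plumbing: normalized
#' anatomy/SUV channels stacked with the TPDM into the 3-channel composite a
#' downstream 3D segmenter consumes.
#'
#' @param suv un-normalized SUV volume.
#' @param anat co-registered anatomical volume (CT/MR or phantom density) on
#'   the same grid.
#' @param gt optional ground-truth [label_volume()]; required for
#'   truth-dependent segmenters.
#' @param config a [pipeline_config()].
#' @param anat_clip clip window for the anatomical channel; defaults to the
#'   CT window of `config$preprocess`.
#' @return a `tpdm_case` list: `tpdm`, `raw`, `mips`, `predictions`,
#'   `truth_projections`, `channels` (3-channel composite), `frame`, `config`.
#' @export
run_case <- function(suv, anat, gt = NULL, config = pipeline_config(),
                     anat_clip = NULL) {
  stopifnot_same_geometry(suv, anat, "SUV and anatomical volumes")
  if (!is.null(gt)) stopifnot_same_geometry(suv, gt, "SUV and label volumes")
  frame <- projection_frame(suv)
  angles <- make_angles(config$n_angles)
  mips <- mip_stack(suv, angles, frame)
  truth_stack <- if (!is.null(gt)) mip_stack(gt, angles, frame) else NULL
  preds <- segment_stack(mips, config$segmenter, truth_stack)
  raw <- reconstruct_raw(preds, suv)
  tpdm <- postprocess(raw, suv, config$preprocess)
  if (is.null(anat_clip)) anat_clip <- config$preprocess$ct_clip
  anat_norm <- clip_and_normalize(anat, anat_clip[1], anat_clip[2])
  suv_norm <- clip_and_normalize(suv, config$preprocess$suv_clip[1],
                                 config$preprocess$suv_clip[2])
  channels <- stack_channels(anat_norm, suv_norm, tpdm)
  structure(
    list(tpdm = tpdm, raw = raw, mips = mips, predictions = preds,
         truth_projections = truth_stack, channels = channels,
         frame = frame, config = config),
    class = "tpdm_case"
  )
}

#' Stack normalized channels into a composite volume
#'
#' Orders the channels as (anatomy, SUV, TPDM) — the input layout of the
#' 3-channel downstream segmenter. Omitting `tpdm` gives the 2-channel
#' baseline variant.
#'
#' @param anat_norm,suv_norm volumes already normalized to `[0, 1]`.
#' @param tpdm optional TPDM in `[0, 1]`; `NULL` for the baseline composite.
#' @return a `channel_volume`: 4D array `[x, y, z, channel]` with named
#'   channels and the shared geometry.
#' @export
stack_channels <- function(anat_norm, suv_norm, tpdm = NULL) {
  stopifnot_same_geometry(anat_norm, suv_norm, "channels")
  vols <- list(anat = anat_norm, suv = suv_norm)
  if (!is.null(tpdm)) {
    stopifnot_same_geometry(anat_norm, tpdm, "channels")
    vols$tpdm <- tpdm
  }
  for (nm in names(vols)) {
    r <- range(vols[[nm]]$values)
    if (r[1] < -1e-9 || r[2] > 1 + 1e-9)
      stop("channel `", nm, "` is not normalized to [0, 1]")
  }
  d <- dim(anat_norm$values)
  vals <- array(0, c(d, length(vols)))
  for (i in seq_along(vols)) vals[, , , i] <- vols[[i]]$values
  structure(
    list(values = vals, spacing = anat_norm$spacing,
         origin = anat_norm$origin, axes = anat_norm$axes,
         channels = names(vols)),
    class = "channel_volume"
  )
}

#' @export
print.channel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<channel_volume> %d x %d x %d voxels, %d channel(s): %s\n",
              d[1], d[2], d[3], d[4], paste(x$channels, collapse = ", ")))
  invisible(x)
}

patch_origins <- function(extent, size, stride) {
  if (size > extent) stop("patch size exceeds volume extent; pad_to() first")
  o <- seq.int(1L, extent - size + 1L, by = stride)
  last <- extent - size + 1L
  if (o[length(o)] != last) o <- c(o, last)  # clamp final patch to the edge
  o
}

#' Sliding-window patch extraction
#'
#' Extracts patches on a regular grid with per-axis stride
#' `floor(size * (1 - overlap))`; the final origin per axis is clamped so the
#' last patch ends exactly at the volume edge. Every voxel is covered by at
#' least one patch. Works on 3D volumes and on `channel_volume` composites
#' (the channel axis is carried whole into every patch).
#'
#' @param vol a `scalar_volume`, `channel_volume`, or plain 3D/4D array.
#' @param size integer length-3 patch dimensions.
#' @param overlap overlap fraction in `[0, 1)`.
#' @return a `patch_set`: list of patches (each with `values` and 1-based
#'   `origin`), plus the source dims/size needed by [reassemble_patches()].
#' @export
extract_patches <- function(vol, size = c(160, 160, 160), overlap = 0.25) {
  if (overlap < 0 || overlap >= 1) stop("`overlap` must lie in [0, 1)")
  vals <- if (is.array(vol)) vol else vol$values
  d <- dim(vals)
  spatial <- d[1:3]
  size <- as.integer(size)
  stride <- pmax(as.integer(floor(size * (1 - overlap))), 1L)
  ox <- patch_origins(spatial[1], size[1], stride[1])
  oy <- patch_origins(spatial[2], size[2], stride[2])
  oz <- patch_origins(spatial[3], size[3], stride[3])
  grid <- expand.grid(x = ox, y = oy, z = oz)
  patches <- lapply(seq_len(nrow(grid)), function(i) {
    o <- as.integer(unlist(grid[i, ]))
    p <- if (length(d) == 4L)
      vals[o[1]:(o[1] + size[1] - 1), o[2]:(o[2] + size[2] - 1),
           o[3]:(o[3] + size[3] - 1), , drop = FALSE]
    else
      vals[o[1]:(o[1] + size[1] - 1), o[2]:(o[2] + size[2] - 1),
           o[3]:(o[3] + size[3] - 1), drop = FALSE]
    list(values = p, origin = o)
  })
  structure(
    list(patches = patches, source_dim = d, size = size, stride = stride,
         overlap = overlap),
    class = "patch_set"
  )
}

#' Reassemble a volume from sliding-window patches
#'
#' Places every patch back at its origin; overlapping voxels are averaged,
#' which is an exact inverse when overlapping patches agree (as they do for
#' patches of one volume).
#'
#' @param ps a `patch_set` from [extract_patches()].
#' @return array with the source dimensions.
#' @export
reassemble_patches <- function(ps) {
  d <- ps$source_dim
  acc <- array(0, d)
  cnt <- array(0, d)
  for (p in ps$patches) {
    o <- p$origin; s <- ps$size
    ix <- o[1]:(o[1] + s[1] - 1); iy <- o[2]:(o[2] + s[2] - 1)
    iz <- o[3]:(o[3] + s[3] - 1)
    if (length(d) == 4L) {
      acc[ix, iy, iz, ] <- acc[ix, iy, iz, ] + p$values
      cnt[ix, iy, iz, ] <- cnt[ix, iy, iz, ] + 1
    } else {
      acc[ix, iy, iz] <- acc[ix, iy, iz] + p$values
      cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
    }
  }
  acc / cnt
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Computes the full 3D metric suite for one case: voxel-wise Dice, HD95 (mm),
#' lesion-wise TP/FN/FP with sensitivity and precision (18-connectivity,
#' > 0.5 ml components), predicted and true MTV (ml), and SUVmax over each
#' mask when an SUV volume is given.
#'
#' @param pred,gt binary masks on one geometry.
#' @param suv optional SUV volume for SUVmax.
#' @param spacing voxel spacing (taken from volumes if omitted).
#' @param min_volume_ml lesion-component volume filter (ml).
#' @param case_id optional identifier column.
#' @return a one-row tibble.
#' @export
evaluate_segmentation <- function(pred, gt, suv = NULL, spacing = NULL,
                                  min_volume_ml = 0.5, case_id = NA_character_) {
  sp <- mask_spacing(pred, spacing)
  lc <- lesion_counts(pred, gt, sp, min_volume_ml = min_volume_ml)
  tibble::tibble(
    case_id = case_id,
    dice = as.numeric(dice(pred, gt)),
    hd95_mm = suppressWarnings(hd95(pred, gt, sp)),
    tp = lc$tp, fn = lc$fn, fp = lc$fp,
    sensitivity = lc$sensitivity, precision = lc$precision,
    mtv_ml = mtv(pred, sp), mtv_true_ml = mtv(gt, sp),
    suvmax = if (!is.null(suv)) suvmax(suv, pred) else NA_real_,
    suvmax_true = if (!is.null(suv)) suvmax(suv, gt) else NA_real_
  )
}

#' Projection-count study
#'
#' Measures TPDM quality as a function of the number of projections: for each
#' count `n` the angles are regenerated uniformly over `[0, 180)`, stages 1-2
#' are rerun, and the HD95 (mm) between the binarized post-processed TPDM and
#' the ground truth is recorded. With more projections the accumulated
#' evidence concentrates, so the curve characteristically decreases sharply
#' and then saturates.
#'
#' The default binarization threshold is `tau = 0.5`: on the max-normalized
#' TPDM this is "half-maximal accumulated evidence" and is scale-free in the
#' projection count, so curves for different `n` are comparable (see the
#' methods vignette for why the support threshold `tau = 0` is unsuitable
#' here).
#'
#' @param cases list of cases, each a list with at least `suv` and `gt`
#'   (e.g. from [generate_phantom()]).
#' @param counts projection counts to evaluate (default `c(1, 2, 4, 9, 18, 36)`).
#' @param segmenter a [segmenter_spec()].
#' @param tau TPDM binarization threshold.
#' @param preprocess a [preprocess_config()].
#' @return a `tpdm_study`: list with `results` (tibble: case, n_angles,
#'   hd95_mm, flagged) and `summary` (mean HD95 per count over unflagged
#'   cases).
#' @export
projection_count_study <- function(cases, counts = c(1, 2, 4, 9, 18, 36),
                                   segmenter = segmenter_spec("oracle"),
                                   tau = 0.5,
                                   preprocess = preprocess_config()) {
  rows <- list()
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    if (is.null(cs$gt)) stop("case ", ci, " has no ground truth")
    frame <- projection_frame(cs$suv)
    for (n in sort(counts)) {
      angles <- make_angles(n)
      mips <- mip_stack(cs$suv, angles, frame)
      truth <- mip_stack(cs$gt, angles, frame)
      preds <- segment_stack(mips, segmenter, truth)
      raw <- reconstruct_raw(preds, cs$suv)
      tp <- postprocess(raw, cs$suv, preprocess)
      mask <- binarize_tpdm(tp, tau)
      flagged <- sum(mask$values) == 0 || sum(cs$gt$values) == 0
      hd <- if (flagged) NA_real_ else hd95(mask, cs$gt)
      rows[[length(rows) + 1]] <- tibble::tibble(
        case = ci, n_angles = n, hd95_mm = hd, flagged = flagged
      )
    }
  }
  results <- do.call(rbind, rows)
  ok <- !results$flagged & is.finite(results$hd95_mm)
  summary <- if (any(ok))
    stats::aggregate(hd95_mm ~ n_angles, data = results[ok, ], FUN = mean)
  else data.frame(n_angles = numeric(), hd95_mm = numeric())
  structure(
    list(results = tibble::as_tibble(results),
         summary = tibble::as_tibble(summary), tau = tau),
    class = "tpdm_study"
  )
}

#' @export
print.tpdm_study <- function(x, ...) {
  cat("<tpdm_study> mean HD95 (mm) by projection count, tau =", x$tau, "\n")
  print(x$summary)
  invisible(x)
}

#' Compare two cohort metric tables
#'
#' Computes per-case metric differences (method A minus method B), a
#' two-sided Wilcoxon signed-rank p-value per shared metric, and — when MTV
#' columns are present — the Pearson correlation of predicted vs true
#' patient-wise MTV for each run.
#'
#' @param metrics_a,metrics_b tibbles as produced by
#'   [evaluate_segmentation()], one row per case, sharing `case_id` values.
#' @return a `paired_comparison`: `deltas` tibble, `tests` tibble
#'   (metric, p_value, method), and `mtv_pcc` per run.
#' @export
compare_runs <- function(metrics_a, metrics_b) {
  if (!all(metrics_a$case_id %in% metrics_b$case_id) ||
      nrow(metrics_a) != nrow(metrics_b))
    stop("the two tables must cover the same case identifiers")
  b <- metrics_b[match(metrics_a$case_id, metrics_b$case_id), ]
  num <- intersect(names(metrics_a), names(b))
  num <- num[vapply(metrics_a[num], is.numeric, logical(1))]
  num <- setdiff(num, c("mtv_true_ml", "suvmax_true"))
  deltas <- tibble::tibble(case_id = metrics_a$case_id)
  tests <- list()
  for (m in num) {
    deltas[[paste0("delta_", m)]] <- metrics_a[[m]] - b[[m]]
    ok <- is.finite(metrics_a[[m]]) & is.finite(b[[m]])
    w <- wilcoxon_signed_rank(metrics_a[[m]][ok], b[[m]][ok])
    tests[[m]] <- tibble::tibble(metric = m, p_value = w$p_value,
                                 method = w$method)
  }
  mtv_pcc <- c(a = NA_real_, b = NA_real_)
  if (all(c("mtv_ml", "mtv_true_ml") %in% names(metrics_a))) {
    mtv_pcc["a"] <- pcc(metrics_a$mtv_ml, metrics_a$mtv_true_ml)
    mtv_pcc["b"] <- pcc(b$mtv_ml, b$mtv_true_ml)
  }
  structure(
    list(deltas = deltas, tests = do.call(rbind, tests), mtv_pcc = mtv_pcc),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat("<paired_comparison>\n")
  print(x$tests)
  cat(sprintf("MTV PCC: run A %.4f, run B %.4f\n", x$mtv_pcc["a"],
              x$mtv_pcc["b"]))
  invisible(x)
}
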