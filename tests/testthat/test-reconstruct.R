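test_that("backprojection traces rays through the reference grid", {
  ref <- scalar_volume(array(0, c(16, 16, 8)), c(2, 2, 3))
  fr <- projection_frame(ref)
  nz <- fr$iso_dim[3]; side <- fr$side
  # all-zero mask -> all-zero volume
  zero <- projection_image(matrix(0, nz, side), c(3, 2), 0, "ground-truth")
  expect_true(all(backproject_mask(zero, 0, ref, fr)$values == 0))
  # all-one mask at theta = 0 -> full shadow over the whole reference grid
  one <- projection_image(matrix(1, nz, side), c(3, 2), 0, "ground-truth")
  expect_true(all(backproject_mask(one, 0, ref, fr)$values == 1))
  # single on-axis pixel at one row -> a straight line along y at that slice
  m <- matrix(0, nz, side)
  ctr_col <- (side + 1) %/% 2
  m[5, ctr_col] <- 1
  bp <- backproject_mask(projection_image(m, c(3, 2), 0, "ground-truth"),
                         0, ref, fr)
  hits <- which(bp$values > 0, arr.ind = TRUE)
  # ray-membership oracle: x = ctr_col - pad, all y, z = 5
  expect_true(all(hits[, 1] == ctr_col - fr$pre[1]))
  expect_true(all(hits[, 3] == 5))
  expect_identical(nrow(hits), 16L)  # one voxel per y along the ray
  # frame mismatch is rejected
  bad <- projection_image(matrix(0, nz + 2, side), c(3, 2), 0, "ground-truth")
  expect_error(backproject_mask(bad, 0, ref, fr), "frame")
})

test_that("oracle reconstruction saturates every interior lesion voxel", {
  ph <- sphere_case(dims = c(48, 48, 40), spacing = c(2, 2, 3), radius_mm = 16)
  angles <- make_angles(12)
  fr <- projection_frame(ph$suv)
  masks <- segment_stack(mip_stack(ph$suv, angles, fr),
                         segmenter_spec("oracle"),
                         mip_stack(ph$gt, angles, fr))
  raw <- reconstruct_raw(masks, ph$suv)
  expect_identical(raw$n_angles, 12L)
  # conservation: counts never exceed the number of angles
  expect_lte(max(raw$values), 12)
  # interior ground-truth voxels reach the full count
  interior <- erode26(ph$gt$values)
  expect_gt(sum(interior), 0)
  expect_equal(min(raw$values[interior > 0]), 12)
  # superset property: maximal-count voxels cover >= 99% of the lesion
  expect_gte(mean(raw$values[ph$gt$values > 0] >= 12 - 1e-9), 0.99)
})

test_that("single-angle reconstruction is the swept cylinder of the shadow", {
  ph <- sphere_case(dims = c(32, 32, 24), spacing = c(2, 2, 3), radius_mm = 10)
  angles <- make_angles(1)
  fr <- projection_frame(ph$gt)
  truth_stack <- mip_stack(ph$gt, angles, fr)
  masks <- segment_stack(mip_stack(ph$suv, angles, fr),
                         segmenter_spec("oracle"), truth_stack)
  raw <- reconstruct_raw(masks, ph$suv)
  # cylinder membership oracle at theta = 0: voxel in iff (x, z) in the
  # projected mask footprint, for every y
  m <- truth_stack$images[[1]]$values  # rows z, cols padded x
  d <- dim(ph$gt$values)
  expected <- array(0, d)
  for (x in seq_len(d[1])) for (z in seq_len(d[3]))
    if (m[z, x + fr$pre[1]] > 0) expected[x, , z] <- 1
  expect_equal(raw$values, expected)
})

test_that("accumulation shrinks the maximal-count core on nested angle sets", {
  ph <- sphere_case(dims = c(32, 32, 24), spacing = c(2, 2, 3), radius_mm = 10)
  fr <- projection_frame(ph$suv)
  core_count <- vapply(c(1, 2, 4), function(n) {
    angles <- make_angles(n)
    masks <- segment_stack(mip_stack(ph$suv, angles, fr),
                           segmenter_spec("oracle"),
                           mip_stack(ph$gt, angles, fr))
    raw <- reconstruct_raw(masks, ph$suv)
    sum(raw$values >= n - 1e-9)
  }, numeric(1))
  expect_true(all(diff(core_count) <= 0))
})

test_that("post-processing gates by clipped SUV, normalizes, and cuts the bottom percentile", {
  # zero raw -> zero TPDM
  raw0 <- mk_raw(array(0, c(10, 10, 10)), c(2, 2, 2), 4)
  suv <- scalar_volume(array(1, c(10, 10, 10)), c(2, 2, 2))
  tp0 <- postprocess(raw0, suv)
  expect_true(all(tp0$values == 0))
  # equal raw counts at SUV 7 and SUV 12 get equal TPDM values (both gated to 5)
  raw <- raw0
  raw$values[2, 2, 2] <- 3; raw$values[8, 8, 8] <- 3
  raw$values[5, 5, 5] <- 3  # reference voxel at SUV 1 to avoid a trivial max
  suv2 <- suv
  suv2$values[2, 2, 2] <- 7; suv2$values[8, 8, 8] <- 12
  tp <- postprocess(raw, suv2, preprocess_config(percentile_cut = 5))
  expect_equal(tp$values[2, 2, 2], tp$values[8, 8, 8])
  expect_equal(max(tp$values), 1)
  # zero wherever raw was zero
  expect_true(all(tp$values[raw$values == 0] == 0))
  expect_error(postprocess(raw, scalar_volume(array(1, c(5, 5, 5)), c(2, 2, 2))),
               "share grid dimensions")
})

test_that("the percentile step removes 5% of distinct positive values", {
  # continuous synthetic product volume with ~40k distinct positives
  set.seed(12)
  d <- c(40, 40, 30)
  vals <- array(0, d)
  pos_idx <- sample(prod(d), 40000)
  vals[pos_idx] <- sample(1:8, 40000, replace = TRUE)
  raw <- mk_raw(vals, c(2, 2, 3), 8)
  suv <- scalar_volume(array(runif(prod(d), 0.2, 4), d), c(2, 2, 3))
  tp <- postprocess(raw, suv, preprocess_config(percentile_cut = 5))
  frac <- tp$provenance$fraction_zeroed
  expect_lt(abs(frac - 0.05), 0.001)
})

test_that("binarization thresholds nest and default to the support", {
  ph <- sphere_case(dims = c(24, 24, 16), spacing = c(2, 2, 3), radius_mm = 8,
                    noise_sd = 0.1)
  case <- run_case(ph$suv, ph$anat, ph$gt, pipeline_config(n_angles = 6))
  m0 <- binarize_tpdm(case$tpdm, 0)
  expect_equal(m0$values, (case$tpdm$values > 0) * 1)
  m1 <- binarize_tpdm(case$tpdm, 0.3)
  m2 <- binarize_tpdm(case$tpdm, 0.7)
  expect_true(all(m2$values <= m1$values))
  expect_true(all(m1$values <= m0$values))
  zero <- binarize_tpdm(scalar_volume(array(0, dim(ph$suv$values)),
                                      ph$suv$spacing), 0)
  expect_true(all(zero$values == 0))
  expect_error(binarize_tpdm(case$tpdm, 1), "tau")
})
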