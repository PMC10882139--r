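test_that("make_angles generates the uniform half-open angle families", {
  a36 <- make_angles(36)
  expect_identical(a36$n, 36L)
  expect_equal(a36$angles, seq(0, 175, by = 5))
  expect_equal(unique(diff(a36$angles)), 5)
  expect_equal(make_angles(1)$angles, 0)
  expect_equal(make_angles(4)$angles, c(0, 45, 90, 135))
  expect_error(make_angles(0), "positive")
})

test_that("axial rotation: identity at 0, exact transpose form at 90, fixed center", {
  set.seed(3)
  v <- scalar_volume(array(rnorm(9 * 9 * 4), c(9, 9, 4)), c(2, 2, 3))
  expect_equal(rotate_axial(v, 0, "nearest")$values, v$values)
  expect_equal(rotate_axial(v, 0, "linear")$values, v$values, tolerance = 1e-12)
  # 90 deg CCW has an exact integer-grid form: out[i, j] = in[j, N+1-i]
  r90 <- rotate_axial(v, 90, "nearest")
  oracle <- v$values
  for (k in 1:4) oracle[, , k] <- t(v$values[, 9:1, k])
  expect_equal(r90$values, oracle)
  # a point at the slice center is a fixed point at any angle
  w <- scalar_volume(array(0, c(9, 9, 4)), c(2, 2, 3))
  w$values[5, 5, 2] <- 7
  for (th in c(13, 45, 110, 170))
    expect_equal(rotate_axial(w, th, "nearest")$values[5, 5, 2], 7)
  expect_error(rotate_axial(v, 10, "spline"))
  aniso <- scalar_volume(array(0, c(4, 4, 4)), c(1, 2, 3))
  expect_error(rotate_axial(aniso, 10), "isotropic")
})

test_that("MIP preserves the global maximum and projects on-axis points invariantly", {
  ph <- sphere_case(dims = c(32, 32, 24), spacing = c(2, 2, 3), radius_mm = 10)
  fr <- projection_frame(ph$suv)
  for (th in c(0, 35, 90, 145)) {
    m <- mip(ph$suv, th, fr, interpolation = "nearest")
    expect_equal(max(m$values), max(ph$suv$values))
  }
  # single voxel on the rotation axis appears at the same pixel at all angles;
  # the rotation center is the padded frame center: side 23, pad 3 -> index 12
  v <- scalar_volume(array(0, c(16, 16, 8)), c(2, 2, 3))
  v$values[9, 9, 5] <- 9
  fr2 <- projection_frame(v)
  expect_identical(fr2$side %% 2L, 1L)
  expect_identical(fr2$pre[1] + 9L, (fr2$side + 1L) %/% 2L)
  pos <- lapply(c(0, 30, 60, 120), function(th) {
    m <- mip(v, th, fr2, interpolation = "nearest")
    which(m$values == 9, arr.ind = TRUE)
  })
  expect_true(all(vapply(pos, nrow, 1L) == 1))
  expect_equal(length(unique(vapply(pos, function(p) p[1, 1], 1))), 1)  # row z
  expect_equal(length(unique(vapply(pos, function(p) p[1, 2], 1))), 1)  # center col
})

test_that("MIP of a constant volume is constant over the footprint", {
  v <- scalar_volume(array(4, c(10, 10, 6)), c(2, 2, 3))
  m <- mip(v, 0, interpolation = "nearest")
  expect_true(all(m$values %in% c(0, 4)))
  # footprint columns (the original x range inside the padded frame) are 4
  fr <- projection_frame(v)
  cols <- fr$pre[1] + seq_len(10)
  expect_true(all(m$values[, cols] == 4))
})

test_that("thresholded MIP of a sphere has disc area within 2% at every angle", {
  r_mm <- 26
  ph <- sphere_case(dims = c(72, 72, 60), spacing = c(1, 1, 1),
                    radius_mm = r_mm, peak_suv = 8)
  # use the binary label projection: voxelized disc vs analytic pi r^2
  fr <- projection_frame(ph$gt)
  for (th in c(0, 25, 70, 115, 160)) {
    p <- project_label(ph$gt, th, fr)
    area_px <- sum(p$values) * prod(p$pixel_spacing)
    expect_lt(abs(area_px - pi * r_mm^2) / (pi * r_mm^2), 0.02)
  }
})

test_that("label projection merges lesions along the ray and separates them across", {
  v <- array(0, c(24, 24, 8))
  # two blobs aligned along y (the theta = 0 projection axis)
  v[11:13, 5:7, 4:5] <- 1
  v[11:13, 17:19, 4:5] <- 1
  lab <- label_volume(v, c(2, 2, 3))
  fr <- projection_frame(lab)
  p0 <- project_label(lab, 0, fr)
  p90 <- project_label(lab, 90, fr)
  n_comp <- function(img) attr(label_components(img$values, 8), "n")
  expect_identical(n_comp(p0), 1L)
  expect_identical(n_comp(p90), 2L)
  # empty and full labels
  empty <- label_volume(array(0, c(8, 8, 4)), c(2, 2, 3))
  expect_true(all(project_label(empty, 45)$values == 0))
})

test_that("mip_stack yields one image per angle on one shared frame", {
  ph <- sphere_case(dims = c(24, 24, 16), spacing = c(2, 2, 3), radius_mm = 8)
  st <- mip_stack(ph$suv, make_angles(36))
  expect_length(st$images, 36)
  dims <- unique(lapply(st$images, function(im) dim(im$values)))
  expect_length(dims, 1)
  # empty volume -> all-empty projections
  z <- scalar_volume(array(0, c(8, 8, 8)), c(2, 2, 3))
  stz <- mip_stack(z, make_angles(5))
  expect_true(all(vapply(stz$images, function(im) all(im$values == 0), TRUE)))
})

test_that("mirror symmetry: the MIP at theta+180 is the left-right flip", {
  ph <- sphere_case(dims = c(28, 28, 20), spacing = c(2, 2, 3), radius_mm = 9,
                    noise_sd = 0)
  # off-center second lesion to break accidental symmetry
  ctr <- (c(28, 28, 20) - 1) * c(2, 2, 3) / 2
  ph2 <- generate_phantom(phantom_spec(
    dims = c(28, 28, 20), spacing = c(2, 2, 3),
    lesions = list(
      list(center = ctr + c(10, 4, 6), radii = c(6, 6, 6), peak_suv = 8),
      list(center = ctr - c(8, 10, 6), radii = c(5, 5, 5), peak_suv = 6)
    ),
    noise = list(kind = "none", sd = 0), seed = 2
  ))
  fr <- projection_frame(ph2$suv)
  for (th in c(0, 40, 95)) {
    a <- mip(ph2$suv, th, fr)$values
    b <- mip(ph2$suv, th + 180, fr)$values
    flipped <- b[, ncol(b):1]
    expect_lt(mean(abs(a - flipped)), 0.02 * max(a))
  }
})

test_that("projection is monotone in the volume under nearest interpolation", {
  set.seed(9)
  base <- array(runif(16 * 16 * 8, 0, 5), c(16, 16, 8))
  extra <- array(runif(16 * 16 * 8, 0, 2), c(16, 16, 8))
  A <- scalar_volume(base, c(2, 2, 3))
  B <- scalar_volume(base + extra, c(2, 2, 3))
  fr <- projection_frame(A)
  for (th in c(0, 30, 75, 120)) {
    ma <- mip(A, th, fr, interpolation = "nearest")$values
    mb <- mip(B, th, fr, interpolation = "nearest")$values
    expect_true(all(mb - ma >= -1e-12))
  }
})

test_that("every interior label voxel's shadow is covered in its projection", {
  set.seed(5)
  v <- array(0, c(24, 24, 12))
  centers <- cbind(c(6, 17, 12, 8), c(7, 16, 6, 18), c(4, 9, 6, 8))
  for (r in seq_len(nrow(centers))) {
    cc <- centers[r, ]
    v[cc[1] + (-1:1), cc[2] + (-1:1), cc[3] + (-1:1)] <- 1
  }
  lab <- label_volume(v, c(2, 2, 3))
  fr <- projection_frame(lab)
  for (th in c(0, 20, 55, 125)) {
    p <- project_label(lab, th, fr)
    # trace each blob's interior voxel forward: rotated column, same z row
    cx <- (fr$side + 1) / 2; cy <- (fr$side + 1) / 2
    co <- cos(th * pi / 180); si <- sin(th * pi / 180)
    for (r in seq_len(nrow(centers))) {
      px <- centers[r, 1] + fr$pre[1] - cx
      py <- centers[r, 2] + fr$pre[2] - cy
      col <- round(co * px - si * py + cx)
      expect_identical(p$values[centers[r, 3], col], 1)
    }
  }
})
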