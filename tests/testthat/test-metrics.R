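test_that("dice handles identity, disjoint, partial and both-empty cases", {
  a <- array(0, c(4, 4, 4)); b <- array(0, c(4, 4, 4))
  a[1:2, 1, 1] <- 1
  expect_equal(as.numeric(dice(a, a)), 1)
  b[3:4, 4, 4] <- 1
  expect_equal(as.numeric(dice(a, b)), 0)
  # |P| = |G| = 2, |intersection| = 1
  c1 <- array(0, c(4, 4, 4)); c2 <- array(0, c(4, 4, 4))
  c1[1:2, 1, 1] <- 1; c2[2:3, 1, 1] <- 1
  expect_equal(as.numeric(dice(c1, c2)), 0.5)
  e <- array(0, c(4, 4, 4))
  d_ee <- dice(e, e)
  expect_equal(as.numeric(d_ee), 1)
  expect_true(attr(d_ee, "both_empty"))
  expect_error(dice(a, array(0, c(3, 3, 3))), "dimensions")
})

test_that("FNA/FPA average completely-missed component areas in cm^2", {
  g <- matrix(0, 20, 20); p <- matrix(0, 20, 20)
  # perfect prediction
  g[2:4, 2:4] <- 1
  expect_equal(unname(fna_fpa(g, g, c(2, 2))), c(0, 0))
  # one 10-pixel GT component unhit, pixel area 4 mm^2 -> FNA 0.4 cm^2
  g2 <- matrix(0, 20, 20); g2[5, 1:10] <- 1
  expect_equal(unname(fna_fpa(p, g2, c(2, 2))), c(0.4, 0))
  # one spurious 25-pixel prediction component -> FPA 1.0 cm^2
  p2 <- matrix(0, 20, 20); p2[10:14, 10:14] <- 1
  expect_equal(unname(fna_fpa(p2, matrix(0, 20, 20), c(2, 2))), c(0, 1.0))
  # a touched component does not count even if barely overlapped
  g3 <- matrix(0, 20, 20); g3[2:6, 2:6] <- 1
  p3 <- matrix(0, 20, 20); p3[2, 2] <- 1
  expect_equal(unname(fna_fpa(p3, g3, c(2, 2))), c(0, 0))
})

test_that("18-connectivity joins edges but not corners; 0.5 ml filter is strict", {
  m <- array(0, c(6, 6, 6))
  m[2, 2, 2] <- 1; m[3, 3, 2] <- 1  # edge neighbors (offset 1,1,0)
  expect_identical(nrow(components3d(m, c(1, 1, 1), 0)$components), 1L)
  m2 <- array(0, c(6, 6, 6))
  m2[2, 2, 2] <- 1; m2[3, 3, 3] <- 1  # corner only (offset 1,1,1)
  expect_identical(nrow(components3d(m2, c(1, 1, 1), 0)$components), 2L)
  # 8 voxels at 0.1 ml/voxel (0.8 ml) kept; 4 voxels (0.4 ml) dropped
  sp <- c(5, 5, 4)  # 100 mm^3 = 0.1 ml per voxel
  m3 <- array(0, c(10, 10, 4))
  m3[1:2, 1:2, 1:2] <- 1
  m3[8:9, 8:9, 1] <- 1
  cs <- components3d(m3, sp, min_volume_ml = 0.5)
  expect_identical(nrow(cs$components), 1L)
  expect_equal(cs$components$volume_ml, 0.8)
  expect_error(components3d(array(2, c(3, 3, 3)), c(1, 1, 1)), "binary")
})

test_that("component labeling agrees with an igraph flood-fill reference", {
  skip_if_not_installed("igraph")
  set.seed(101)
  for (rep in 1:30) {
    d <- sample(5:20, 3, replace = TRUE)
    m <- array(rbinom(prod(d), 1, runif(1, 0.05, 0.4)), d)
    lab <- label_components(m, 18)
    oc <- oracle_components(m, offsets_18())
    expect_equal(attr(lab, "n"), oc$n, ignore_attr = TRUE)
    expect_equal(lab, oc$labels, ignore_attr = TRUE, info = paste("rep", rep))
  }
})

test_that("lesion counts classify TP/FN/FP against raw foreground overlap", {
  sp <- c(2, 2, 2)
  gt <- array(0, c(20, 20, 20))
  gt[3:7, 3:7, 3:7] <- 1     # lesion A (1 ml)
  gt[14:18, 14:18, 14:18] <- 1  # lesion B
  pred_eq <- gt
  r <- lesion_counts(pred_eq, gt, sp)
  expect_equal(c(r$tp, r$fn, r$fp), c(2, 0, 0))
  # pred covers lesion A only, plus one spurious blob
  pred <- array(0, c(20, 20, 20))
  pred[3:7, 3:7, 3:7] <- 1
  pred[14:18, 3:7, 14:18] <- 1
  r2 <- lesion_counts(pred, gt, sp)
  expect_equal(c(r2$tp, r2$fn, r2$fp), c(1, 1, 1))
  expect_equal(r2$sensitivity, 0.5)
  expect_equal(r2$precision, 0.5)
  # empty prediction: all FN, undefined precision
  r3 <- lesion_counts(array(0, c(20, 20, 20)), gt, sp)
  expect_equal(c(r3$tp, r3$fn, r3$fp), c(0, 2, 0))
  expect_equal(r3$sensitivity, 0)
  expect_true(is.na(r3$precision))
  # single lesion identity
  one <- array(0, c(12, 12, 12)); one[4:8, 4:8, 4:8] <- 1
  r4 <- lesion_counts(one, one, sp)
  expect_equal(c(r4$tp, r4$fn, r4$fp), c(1, 0, 0))
})

test_that("detection is invariant to padding either mask with background", {
  sp <- c(2, 2, 3)
  gt <- array(0, c(16, 16, 16)); gt[4:9, 4:9, 4:9] <- 1
  pred <- array(0, c(16, 16, 16)); pred[5:10, 5:10, 5:10] <- 1
  base <- lesion_counts(pred, gt, sp)
  big_gt <- array(0, c(24, 24, 24)); big_gt[5:20, 5:20, 5:20] <- gt
  big_pred <- array(0, c(24, 24, 24)); big_pred[5:20, 5:20, 5:20] <- pred
  padded <- lesion_counts(big_pred, big_gt, sp)
  expect_equal(base, padded)
})

test_that("HD95 matches hand-computable cases and is symmetric", {
  sp <- c(2, 2, 3)
  a <- array(0, c(12, 12, 12)); a[4:7, 4:7, 4:7] <- 1
  expect_equal(hd95(a, a, sp), 0)
  # two single voxels: one distance in each direction
  b <- array(0, c(12, 12, 12)); b[2, 2, 2] <- 1
  c_ <- array(0, c(12, 12, 12)); c_[5, 2, 2] <- 1
  expect_equal(hd95(b, c_, sp), 3 * sp[1])
  expect_equal(hd95(b, c_, sp), hd95(c_, b, sp))
  expect_warning(r <- hd95(b, array(0, c(12, 12, 12)), sp), "empty")
  expect_true(is.na(r))
})

test_that("HD95 never exceeds the exact Hausdorff distance from an all-pairs oracle", {
  set.seed(77)
  for (rep in 1:12) {
    d <- sample(6:15, 3, replace = TRUE)
    sp <- runif(3, 1, 3)
    a <- array(0, d); b <- array(0, d)
    # random blobs, guaranteed non-empty
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    a[cbind(sample(d[1], na, TRUE), sample(d[2], na, TRUE),
            sample(d[3], na, TRUE))] <- 1
    b[cbind(sample(d[1], nb, TRUE), sample(d[2], nb, TRUE),
            sample(d[3], nb, TRUE))] <- 1
    expect_lte(hd95(a, b, sp), oracle_hausdorff(a, b, sp) + 1e-9)
  }
})

test_that("MTV and SUVmax follow voxel arithmetic and analytic sphere volume", {
  expect_equal(mtv(array(0, c(5, 5, 5)), c(2, 2, 2)), 0)
  m <- array(0, c(10, 10, 10)); m[1:4, 1:5, 1:5] <- 1  # 100 voxels
  expect_equal(mtv(m, c(2, 2, 2.5)), 1.0)
  ball <- ball_mask(c(32, 32, 32), c(1, 1, 1), c(15.5, 15.5, 15.5), 10)
  expect_lt(abs(mtv(ball, c(1, 1, 1)) - 4 / 3 * pi * 1) / (4 / 3 * pi), 0.03)
  suv <- array(1, c(10, 10, 10)); suv[3, 3, 3] <- 9; suv[9, 9, 9] <- 20
  mm <- array(0, c(10, 10, 10)); mm[1:5, 1:5, 1:5] <- 1
  expect_equal(suvmax(suv, mm), 9)  # the 20 lies outside the mask
  expect_true(is.na(suvmax(suv, array(0, c(10, 10, 10)))))
  # additive over disjoint masks
  m1 <- array(0, c(8, 8, 8)); m1[1:2, , ] <- 1
  m2 <- array(0, c(8, 8, 8)); m2[5:6, , ] <- 1
  expect_equal(mtv(m1 + m2, c(1, 1, 1)), mtv(m1, c(1, 1, 1)) + mtv(m2, c(1, 1, 1)))
})

test_that("Pearson correlation matches closed forms and flags degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pcc(x, 2 * x + 1), 1)
  expect_equal(pcc(x, -x), -1)
  expect_equal(pcc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pcc(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(pcc(c(1, 2), c(1, 2))))
  expect_error(pcc(1:3, 1:4), "equal length")
})

test_that("Wilcoxon signed-rank: exact cases, undefined case, and enumeration oracle", {
  # all differences zero -> undefined
  expect_true(is.na(wilcoxon_signed_rank(1:5, 1:5)$p_value))
  # n = 6, all positive differences: p = 2 / 2^6
  r <- wilcoxon_signed_rank(11:16, (11:16) - (1:6) / 10)
  expect_equal(r$p_value, 2 / 2^6)
  expect_identical(r$method, "exact")
  # randomized agreement with the full 2^n enumeration oracle
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    a <- round(rnorm(n), 1)
    b <- round(rnorm(n), 1)
    expect_equal(wilcoxon_signed_rank(a, b)$p_value, oracle_wilcoxon(a, b),
                 info = paste("rep", rep))
  }
})

test_that("Wilcoxon exact branch agrees with stats::wilcox.test on tie-free data", {
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(6:11, 1)
    a <- rnorm(n); b <- rnorm(n)  # continuous: no ties, no zeros a.s.
    ours <- wilcoxon_signed_rank(a, b)$p_value
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12, info = paste("rep", rep))
  }
})

test_that("large-sample branch uses the tie-corrected normal approximation", {
  set.seed(55)
  a <- rnorm(40); b <- rnorm(40, 0.3)
  ours <- wilcoxon_signed_rank(a, b)
  expect_identical(ours$method, "normal-approximation")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(ours$p_value, ref, tolerance = 1e-10)
})
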