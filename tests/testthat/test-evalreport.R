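test_that("binarization applies the >= threshold convention", {
  z <- array(0, dim = c(3, 3, 2))
  expect_equal(sum(binarize(z)$voxels), 0)
  half <- array(0.5, dim = c(2, 2, 1))
  expect_true(all(binarize(half, 0.5)$voxels == 1))  # tie -> foreground
  set.seed(5)
  p <- array(runif(60), dim = c(3, 4, 5))
  expect_identical(binarize(p, 0.3)$voxels,
                   array(as.integer(p >= 0.3), dim = dim(p)))
  expect_error(binarize(p, 0), "threshold")
  expect_error(binarize(p, 1), "threshold")
})

test_that("segmentation metrics match the defining count ratios", {
  g <- rand_mask(c(5, 5, 2), p = 0.4, seed = 2)
  expect_equal(seg_metrics(g, g)$dice, 1)
  expect_equal(seg_metrics(g, g)$recall, 1)

  a <- mask_volume(array(c(1, 1, 0, 0, rep(0, 21)) * 1L, dim = c(5, 5, 1)))
  b <- mask_volume(array(c(0, 0, 1, 1, rep(0, 21)) * 1L, dim = c(5, 5, 1)))
  m <- seg_metrics(a, b)
  expect_equal(c(m$dice, m$iou, m$precision, m$recall), c(0, 0, 0, 0))

  # TP=2, FP=1, FN=1 hand computation
  pred <- mask_volume(array(c(1, 1, 1, 0, rep(0, 12)) * 1L, dim = c(4, 4, 1)))
  gt <- mask_volume(array(c(1, 1, 0, 1, rep(0, 12)) * 1L, dim = c(4, 4, 1)))
  m2 <- seg_metrics(pred, gt)
  expect_equal(m2$dice, 2 / 3)
  expect_equal(m2$iou, 1 / 2)
  expect_equal(m2$precision, 2 / 3)
  expect_equal(m2$recall, 2 / 3)

  # empty-vs-empty and empty-vs-nonempty conventions
  e <- mask_volume(array(0L, dim = c(4, 4, 1)))
  expect_equal(seg_metrics(e, e)$dice, 1)
  expect_equal(seg_metrics(e, gt)$dice, 0)
})

test_that("metrics agree with a brute-force oracle on random grids", {
  for (s in 1:25) {
    set.seed(s)
    p <- array(as.integer(runif(64) < 0.5), dim = c(8, 8, 1))
    g <- array(as.integer(runif(64) < 0.5), dim = c(8, 8, 1))
    m <- seg_metrics(mask_volume(p), mask_volume(g))
    tp <- 0; fp <- 0; fn <- 0
    for (i in 1:64) {                 # exhaustive voxel loop
      if (p[i] == 1 && g[i] == 1) tp <- tp + 1
      if (p[i] == 1 && g[i] == 0) fp <- fp + 1
      if (p[i] == 0 && g[i] == 1) fn <- fn + 1
    }
    expect_equal(m$dice, 2 * tp / (2 * tp + fp + fn))
    expect_equal(m$iou, tp / (tp + fp + fn))
    expect_equal(m$precision, tp / (tp + fp))
    expect_equal(m$recall, tp / (tp + fn))
    if (m$iou > 0)                    # identity from the two definitions
      expect_equal(m$dice, 2 * m$iou / (1 + m$iou))
  }
})

test_that("lesion matching stratifies disjoint components by volume", {
  dims <- c(16, 16, 8)
  gt <- array(0L, dim = dims)
  pred <- array(0L, dim = dims)
  expect_true(all(lesion_match(mask_volume(pred), mask_volume(gt))$fp_by_bin
                  == 0))

  # identical masks: no FP, no FN
  gt[2:3, 2:3, 2:3] <- 1L
  lm0 <- lesion_match(mask_volume(gt), mask_volume(gt))
  expect_true(all(lm0$fp_by_bin == 0) && all(lm0$fn_by_bin == 0))

  # one predicted 25-voxel (25 mm^3) blob disjoint from gt -> large-bin FP
  pred2 <- array(0L, dim = dims)
  pred2[10:14, 10:14, 5] <- 1L
  lm1 <- lesion_match(mask_volume(pred2), mask_volume(gt))
  expect_identical(unname(lm1$fp_by_bin), c(0L, 0L, 1L))

  # one 8 mm^3 ground-truth lesion entirely missed -> small-bin FN
  gt2 <- array(0L, dim = dims)
  gt2[5:6, 5:6, 5:6] <- 1L
  lm2 <- lesion_match(mask_volume(array(0L, dim = dims)), mask_volume(gt2))
  expect_identical(unname(lm2$fn_by_bin), c(1L, 0L, 0L))

  # accounting identity: FPs + matched predicted components = all components
  set.seed(8)
  pr <- rand_mask(dims, p = 0.08, seed = 31)
  gr <- rand_mask(dims, p = 0.08, seed = 32)
  lm3 <- lesion_match(pr, gr)
  expect_identical(sum(lm3$fp_by_bin) + lm3$n_matched_pred,
                   lm3$n_pred_components)
  expect_error(lesion_match(mask_volume(pred2), mask_volume(gt),
                            spacing = c(1, 1, 1), threshold = 0.5), NA)
})

test_that("connected components use 26-connectivity", {
  a <- array(0L, dim = c(4, 4, 2))
  a[1, 1, 1] <- 1L
  a[2, 2, 2] <- 1L   # diagonal in all three axes: one component under 26-conn
  lab <- label_components(a)
  expect_identical(attr(lab, "n_components"), 1L)
  b <- array(0L, dim = c(5, 5, 1))
  b[1, 1, 1] <- 1L
  b[1, 3, 1] <- 1L   # gap of one: two components
  expect_identical(attr(label_components(b), "n_components"), 2L)
})

test_that("carbon footprint is linear and reproduces the printed per-fold values", {
  expect_equal(carbon_footprint(0), 0)
  expect_equal(carbon_footprint(3600), 0.475)
  expect_equal(round(carbon_footprint(75 * 60), 2), 0.59)
  expect_equal(round(carbon_footprint(25 * 60), 2), 0.20)
  expect_equal(round(carbon_footprint(16 * 60), 2), 0.13)
  tt <- c(100, 200, 700)
  expect_equal(carbon_footprint(2 * tt), 2 * carbon_footprint(tt))
  expect_error(carbon_footprint(-1), "contract")
})

test_that("normalized footprint follows the literal definition", {
  expect_equal(normalized_cfp(0.3, 0.5, 0.5), 1)        # degenerate bounds
  expect_equal(normalized_cfp(0.5, 0.5, 0.2), 1 - 0.3)  # cfp = cfp_max
  expect_equal(normalized_cfp(0.13, 0.59, 0.13),
               1 - (0.59 - 0.13) * (0.13 / 0.59))
  # monotonically decreasing in cfp for fixed bounds
  vals <- normalized_cfp(seq(0.1, 0.6, by = 0.1), 0.6, 0.1)
  expect_true(all(diff(vals) < 0))
  expect_error(normalized_cfp(0.1, 0, 0), "contract")
})

test_that("improvement statistics reproduce the headline arithmetic", {
  mt <- data.frame(method = c("WV", "BRS_OV"), dice = c(0.414, 0.640))
  et <- data.frame(method = c("WV", "BRS_OV"), cfp = c(0.59, 0.13))
  st <- improvement_stats(mt, et)
  expect_equal(st$dice_increase_pct, 100 * (0.640 - 0.414) / 0.414)
  expect_equal(st$energy_ratio_pct, 100 * 0.59 / 0.13)

  same <- improvement_stats(data.frame(method = c("WV", "BRS_OV"),
                                       dice = c(0.5, 0.5)),
                            data.frame(method = c("WV", "BRS_OV"),
                                       cfp = c(0.2, 0.2)))
  expect_equal(same$dice_increase_pct, 0)
  expect_equal(same$energy_ratio_pct, 100)

  missing <- improvement_stats(mt[1, , drop = FALSE], et)
  expect_false(missing$available)
})
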