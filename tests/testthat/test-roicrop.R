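test_that("vertical extent finds the anterior-posterior support bounds", {
  arr <- array(0, dim = c(8, 60, 3))
  arr[3, 50, 2] <- 1
  expect_equal(unname(vertical_extent(make_image(arr))), c(50, 50))

  blk <- array(0, dim = c(8, 100, 4))
  blk[, 30:79, ] <- 1
  expect_equal(unname(vertical_extent(make_image(blk))), c(30, 79))

  set.seed(6)
  m <- rand_mask(c(10, 40, 5), p = 0.02, seed = 6)
  # brute-force scan over all voxels
  idx <- which(m$voxels != 0, arr.ind = TRUE)
  expect_equal(unname(vertical_extent(m)),
               c(min(idx[, 2]), max(idx[, 2])))

  expect_error(vertical_extent(make_image(array(0, dim = c(4, 4, 2)))),
               "empty-extent")
})

test_that("midline depth is the maximal span at the body midline", {
  # region absent at the midline column -> 0 with a warning
  m <- array(0L, dim = c(20, 30, 3))
  m[2, 5:10, ] <- 1L
  expect_warning(d <- midline_depth(mask_volume(m)), "midline")
  expect_identical(d, 0L)

  # constructed midline run echoing the measured optimal-volume extent
  m2 <- array(0L, dim = c(64, 352, 2))
  m2[33, 10:185, 1] <- 1L   # midline index = floor(64/2) + 1 = 33
  m2[33, 50:60, 2] <- 1L
  expect_identical(midline_depth(mask_volume(m2)), 176L)

  m3 <- array(1L, dim = c(8, 40, 2))
  expect_identical(midline_depth(mask_volume(m3)), 40L)
})

test_that("crop height is the smallest admissible multiple of the divisor", {
  expect_identical(cohort_crop_height(176, 16, 32), 192L)
  expect_identical(cohort_crop_height(100, 16, 32), 128L)
  expect_identical(cohort_crop_height(16, 16, 32), 32L)
  expect_error(cohort_crop_height(340, 16, 32, volume_x = 352),
               "reduce the safe distance")
  expect_error(cohort_crop_height(0, 16, 32), "positive")
})

test_that("lesion slice range spans all lesion-bearing slices", {
  m <- array(0L, dim = c(6, 6, 40))
  m[2, 2, 10:20] <- 1L
  expect_equal(unname(lesion_slice_range(mask_volume(m))), c(10, 20))
  m2 <- array(0L, dim = c(6, 6, 40))
  m2[1, 1, 5] <- 1L; m2[4, 4, 30] <- 1L
  expect_equal(unname(lesion_slice_range(mask_volume(m2))), c(5, 30))
  expect_null(lesion_slice_range(mask_volume(array(0L, dim = c(6, 6, 4)))))
})

test_that("slab harmonization takes the maximal span and contains every lesion", {
  ranges <- list(a = c(10, 20), b = c(3, 44), c = c(15, 34))
  depths <- c(a = 50, b = 50, c = 50)
  h <- harmonize_slab(ranges, depths)
  expect_identical(h$slab_size, 42L)  # spans 11, 42, 20
  for (id in names(ranges)) {
    zs <- h$z_starts[[id]]
    expect_gte(ranges[[id]][1], zs)
    expect_lte(ranges[[id]][2], zs + h$slab_size - 1)
  }
  # single patient: slab equals its own span
  h1 <- harmonize_slab(list(a = c(5, 9)), c(a = 30))
  expect_identical(h1$slab_size, 5L)
  expect_equal(unname(h1$z_starts), 5)
  # lesion range at the volume edge: clamped start still contains it
  h2 <- harmonize_slab(list(a = c(1, 3), b = c(10, 29)), c(a = 40, b = 40))
  expect_equal(unname(h2$z_starts["a"]), 1)
  expect_lte(3, h2$slab_size)
  # shallow patient flagged for oversampling
  h3 <- harmonize_slab(list(a = c(1, 20), b = c(2, 5)), c(a = 30, b = 10))
  expect_true(h3$needs_oversample[["b"]])
})

test_that("dataset variants reproduce the expected shapes and conserve lesions", {
  recs <- small_cohort()
  cs <- compute_crop_spec(recs)
  expect_identical(cs$x_size %% 32L, 0L)

  wv <- build_variant(recs, "WV")
  for (r in recs) {
    p <- wv$patients[[r$patient_id]]
    expect_identical(p$images$pc$voxels, r$pc$voxels)  # untouched
    expect_identical(p$label$voxels, r$lesion_mask$voxels)
  }

  brs <- build_variant(recs, "BRS_WV")
  expect_identical(dim(brs$patients[[1]]$images$pc$voxels), c(96L, 96L, 24L))
  heart <- ovseg:::phantom_heart_mask(c(96, 96, 24))
  expect_true(all(brs$patients[[1]]$images$fpc$voxels[heart > 0] == 0))

  sls <- build_variant(recs, "BRS_SLS", crop = cs)
  ov <- build_variant(recs, "BRS_OV", crop = cs)
  expect_identical(dim(sls$patients[[1]]$label$voxels)[3], cs$z_size)
  expect_identical(dim(ov$patients[[1]]$label$voxels),
                   c(96L, cs$x_size, cs$z_size))
  # foreground-count conservation across all variants
  for (id in names(ov$patients)) {
    n0 <- sum(wv$patients[[id]]$label$voxels)
    expect_identical(sum(sls$patients[[id]]$label$voxels), n0)
    expect_identical(sum(ov$patients[[id]]$label$voxels), n0)
  }
})

test_that("lesions outside the crop are a hard error", {
  recs <- small_cohort()
  cs <- compute_crop_spec(recs)
  bad <- crop_spec(x_start = 64L, x_size = 32L, z_size = cs$z_size,
                   z_starts = cs$z_starts, safe_distance = cs$safe_distance)
  attr(bad, "excluded") <- attr(cs, "excluded")
  attr(bad, "needs_oversample") <- attr(cs, "needs_oversample")
  expect_error(build_variant(recs, "BRS_OV", crop = bad),
               "outside the BRS_OV crop")
})

test_that("lesion-free patients are excluded from the slab variants", {
  recs <- small_cohort()[1:2]
  r <- recs[[2]]
  r$lesion_mask$voxels[] <- 0L
  recs[[2]] <- r
  cs <- compute_crop_spec(recs)
  expect_identical(attr(cs, "excluded"), r$patient_id)
  sls <- build_variant(recs, "BRS_SLS", crop = cs)
  expect_false(r$patient_id %in% names(sls$patients))
  wv <- build_variant(recs, "WV")
  expect_true(r$patient_id %in% names(wv$patients))
})

test_that("shape bookkeeping computes slice and in-plane reductions", {
  red <- shape_reduction(c(352, 352, 150), c(352, 192, 42))
  expect_equal(red$slice_reduction_pct, 72)
  expect_equal(red$inplane_reduction_pct, 100 * (1 - 192 / 352),
               tolerance = 1e-10)
})
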