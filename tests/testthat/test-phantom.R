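test_that("empty configuration yields an empty cohort", {
  cfg <- phantom_config(n_patients = 0L, volume_shape = c(64, 64, 16),
                        lesion_radius_range = c(2, 4),
                        artifact_slices = 0L)
  expect_identical(generate_cohort(cfg), list())
})

test_that("generated records satisfy the containment and geometry contracts", {
  recs <- small_cohort()
  expect_length(recs, 4L)
  for (r in recs) {
    expect_s3_class(r, "patient_record")
    expect_true(r$complete)
    # voxel-wise logical containment: lesion implies region
    expect_true(all(r$lesion_mask$voxels <= r$region_mask$voxels))
    expect_identical(dim(r$pc$voxels), dim(r$lesion_mask$voxels))
    expect_identical(dim(r$pc$voxels), c(96L, 96L, 24L))
    expect_gt(sum(r$lesion_mask$voxels), 0)
  }
})

test_that("lesion-free slice fraction meets the configured minimum", {
  for (r in small_cohort()) {
    z <- dim(r$lesion_mask$voxels)[3]
    per_slice <- colSums(matrix(r$lesion_mask$voxels, ncol = z))
    expect_gte(mean(per_slice == 0), 0.70)
  }
})

test_that("FPC exceeds PC inside lesions and the heart blob", {
  r <- small_cohort()[[1]]
  heart <- ovseg:::phantom_heart_mask(dim(r$pc$voxels))
  les <- r$lesion_mask$voxels > 0
  expect_true(all(r$fpc$voxels[les] > r$pc$voxels[les]))
  expect_true(all(r$fpc$voxels[heart > 0] > r$pc$voxels[heart > 0]))
})

test_that("cohorts are bit-identical across calls with the same config", {
  cfg <- phantom_config(n_patients = 2L, volume_shape = c(48, 48, 16),
                        lesion_radius_range = c(2, 3),
                        artifact_slices = 1L, seed = 11L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # and the NIfTI payloads round-trip bit-identically
  d1 <- withr::local_tempdir()
  write_cohort(a[1], d1)
  v1 <- read_volume(file.path(d1, "phantom001", "pc.nii.gz"))
  expect_equal(v1$voxels, a[[1]]$pc$voxels, tolerance = 1e-6)
})

test_that("full left-breast bias places all lesion centroids on the left", {
  cfg <- phantom_config(n_patients = 3L, volume_shape = c(64, 64, 16),
                        lesion_radius_range = c(2, 4),
                        left_breast_bias = 1, artifact_slices = 0L,
                        seed = 5L)
  for (r in generate_cohort(cfg)) {
    idx <- which(r$lesion_mask$voxels > 0, arr.ind = TRUE)
    lab <- label_components(r$lesion_mask$voxels)
    for (k in seq_len(attr(lab, "n_components"))) {
      cent <- mean(which(lab == k, arr.ind = TRUE)[, 1])
      expect_lt(cent, 32)  # left = small left-right index
    }
  }
})

test_that("invalid configurations name the offending field", {
  expect_error(phantom_config(volume_shape = c(0, 64, 16)), "volume_shape")
  expect_error(phantom_config(lesion_radius_range = c(0, 5)),
               "lesion_radius_range")
  expect_error(phantom_config(lesion_count_range = c(0, 2)),
               "lesion_count_range")
  expect_error(phantom_config(min_lesion_free_slice_fraction = 1),
               "min_lesion_free_slice_fraction")
  expect_error(phantom_config(volume_shape = c(64, 64, 16),
                              lesion_radius_range = c(3, 40)),
               "lesion_radius_range")
  expect_error(phantom_config(volume_shape = c(64, 64, 16),
                              artifact_slices = 10),
               "artifact_slices")
})

test_that("artifact injection touches only the early/late slices, outside the region", {
  cfg <- phantom_config(n_patients = 1L, volume_shape = c(64, 64, 24),
                        lesion_radius_range = c(2, 4),
                        artifact_slices = 0L, seed = 3L)
  rec <- generate_cohort(cfg)[[1]]

  cfg0 <- cfg; cfg0$artifact_slices <- 0L
  expect_identical(inject_artifacts(rec, cfg0), rec)

  cfg3 <- cfg; cfg3$artifact_slices <- 3L
  out <- inject_artifacts(rec, cfg3)
  touched <- vapply(1:24, function(z)
    !identical(out$pc$voxels[, , z], rec$pc$voxels[, , z]), logical(1))
  expect_true(all(touched[c(1:3, 22:24)]))
  expect_false(any(touched[4:21]))
  # lesion mask unchanged; added intensity only outside the region mask
  expect_identical(out$lesion_mask, rec$lesion_mask)
  expect_equal(out$pc$voxels * rec$region_mask$voxels,
               rec$pc$voxels * rec$region_mask$voxels)
})

test_that("full-size default configuration produces 352x352x150 volumes", {
  cfg <- phantom_config(n_patients = 1L)
  expect_identical(cfg$volume_shape, c(352L, 352L, 150L))
  rec <- generate_cohort(cfg)[[1]]
  expect_identical(dim(rec$pc$voxels), c(352L, 352L, 150L))
  expect_identical(dim(rec$lesion_mask$voxels), c(352L, 352L, 150L))
  rm(rec); gc(verbose = FALSE)
})
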