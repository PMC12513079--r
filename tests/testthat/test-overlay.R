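test_that("overlay map is the pixel-wise sum across patients and slices", {
  m1 <- rand_mask(c(6, 7, 1), p = 0.3, seed = 1)
  om1 <- overlay_map(list(m1))
  expect_identical(om1$grid, m1$voxels[, , 1])

  om2 <- overlay_map(list(m1, m1))
  expect_identical(om2$grid, 2L * m1$voxels[, , 1])
  expect_identical(om2$n_patients, 2L)

  cohort <- lapply(1:5, function(s) rand_mask(c(6, 7, 4), p = 0.2, seed = s))
  om <- overlay_map(cohort)
  total <- sum(vapply(cohort, function(m) sum(m$voxels), numeric(1)))
  expect_identical(sum(om$grid), as.integer(total))      # conservation
  expect_lte(max(om$grid), om$n_slices_total)
  expect_identical(om$n_slices_total, 20L)
  # permutation invariance in patient order
  expect_identical(overlay_map(rev(cohort))$grid, om$grid)
  expect_error(overlay_map(list(m1, rand_mask(c(5, 7, 1)))), "alignment")
})

test_that("axis histograms are marginals sharing the grid total", {
  uni <- overlay_map(list(mask_volume(array(1L, dim = c(5, 8, 2)))))
  expect_true(all(axis_histogram(uni, "x") == 10))  # constant profile
  expect_true(all(axis_histogram(uni, "y") == 16))

  om <- overlay_map(lapply(1:3, function(s)
    rand_mask(c(9, 11, 3), p = 0.25, seed = s + 10)))
  hx <- axis_histogram(om, "x")
  hy <- axis_histogram(om, "y")
  expect_equal(sum(hx), sum(hy))
  expect_equal(sum(hx), sum(om$grid))
  # brute-force per-index marginalization
  expect_equal(hx, vapply(seq_len(ncol(om$grid)),
                          function(j) sum(om$grid[, j]), numeric(1)))
  expect_equal(hy, vapply(seq_len(nrow(om$grid)),
                          function(i) sum(om$grid[i, ]), numeric(1)))
})

test_that("midline span measures the non-zero extent of the midline row", {
  g <- matrix(0L, nrow = 64, ncol = 352)
  om <- structure(list(grid = g, n_patients = 1L, n_slices_total = 1L,
                       source_kind = "REGION"), class = "overlay_map")
  expect_identical(midline_span(om)$h_max_mid, 0L)

  g2 <- g; g2[33, 10:185] <- 5L   # midline row = floor(64/2) + 1
  om$grid <- g2
  ms <- midline_span(om)
  expect_identical(ms$h_max_mid, 176L)
  expect_identical(ms$values, g2[33, ])

  g3 <- g; g3[33, ] <- 1L
  om$grid <- g3
  expect_identical(midline_span(om)$h_max_mid, 352L)
})

test_that("optimal-volume region overlays have no wider midline span than whole-volume", {
  recs <- small_cohort()
  cs <- compute_crop_spec(recs)
  brs <- build_variant(recs, "BRS_WV")
  ov <- build_variant(recs, "BRS_OV", crop = cs)
  region_of <- function(dv, rec) {
    # region support inside the variant = non-zero support of the masked PC
    mask_volume(array(as.integer(dv$patients[[rec]]$images$pc$voxels != 0),
                      dim = dim(dv$patients[[rec]]$images$pc$voxels)))
  }
  ids <- names(brs$patients)
  h_wv <- midline_span(overlay_map(lapply(ids, region_of, dv = brs)))
  h_ov <- midline_span(overlay_map(lapply(ids, region_of, dv = ov)))
  expect_lte(h_ov$h_max_mid, h_wv$h_max_mid)
})
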