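test_that("series discovery flags missing series instead of raising", {
  d <- withr::local_tempdir()
  p <- file.path(d, "pat1"); dir.create(p)
  file.create(file.path(p, "pc.nii.gz"))
  file.create(file.path(p, "fpc.nii.gz"))
  rec <- discover_series(p)
  expect_true(rec$complete)
  expect_null(rec$incomplete_reason)

  p2 <- file.path(d, "pat2"); dir.create(p2)
  file.create(file.path(p2, "pc.nii.gz"))
  rec2 <- discover_series(p2)
  expect_false(rec2$complete)
  expect_match(rec2$incomplete_reason, "missing FPC")

  p3 <- file.path(d, "pat3"); dir.create(p3)
  rec3 <- discover_series(p3)
  expect_false(rec3$complete)
  expect_match(rec3$incomplete_reason, "missing PC")
  expect_match(rec3$incomplete_reason, "missing FPC")

  expect_error(discover_series(file.path(d, "nope")), "I/O error")
})

test_that("series description and acquisition time drive classification", {
  d <- withr::local_tempdir()
  vol <- array(sample.int(100, 4 * 6 * 2, replace = TRUE) - 1,
               dim = c(4, 6, 2))
  write_dicom_series(file.path(d, "seriesA"), vol, uid = "1.1",
                     desc = "DYN PRE CONTRAST", acq_time = "100000")
  write_dicom_series(file.path(d, "seriesB"), vol, uid = "1.2",
                     desc = "DYN POST CONTRAST", acq_time = "100100")
  rec <- discover_series(d)
  expect_true(rec$complete)
  expect_match(rec$source_paths$pc, "seriesA")
  expect_match(rec$source_paths$fpc, "seriesB")

  d2 <- withr::local_tempdir()
  write_dicom_series(file.path(d2, "seriesX"), vol, uid = "2.1",
                     desc = "DYN EARLY", acq_time = "100500")
  write_dicom_series(file.path(d2, "seriesY"), vol, uid = "2.2",
                     desc = "DYN LATE", acq_time = "100000")
  rec2 <- suppressMessages(discover_series(d2))
  expect_true(rec2$complete)
  expect_match(rec2$source_paths$pc, "seriesY")   # earlier acquisition
  expect_match(rec2$source_paths$fpc, "seriesX")
})

test_that("a written DICOM series round-trips through the reader", {
  d <- withr::local_tempdir()
  vol <- array(sample.int(2000, 8 * 10 * 5, replace = TRUE) - 1000,
               dim = c(8, 10, 5))
  write_dicom_series(file.path(d, "s"), vol, pixel_spacing = c(0.7, 0.8))
  iv <- dicom_to_nifti(file.path(d, "s"))
  expect_equal(iv$voxels, vol)
  expect_equal(iv$spacing[1:2], c(0.7, 0.8))
  expect_equal(iv$spacing[3], 1)

  # single-slice series gives a Z = 1 volume
  d2 <- withr::local_tempdir()
  write_dicom_series(file.path(d2, "s"), vol[, , 1, drop = FALSE])
  expect_identical(dim(dicom_to_nifti(file.path(d2, "s"))$voxels)[3], 1L)
})

test_that("inconsistent DICOM series raise format errors", {
  vol <- array(1, dim = c(4, 4, 3))
  d <- withr::local_tempdir()
  write_dicom_series(file.path(d, "s"), vol, instances = c(1, 2, 4))
  expect_error(dicom_to_nifti(file.path(d, "s")), "missing instance")

  d2 <- withr::local_tempdir()
  dir.create(file.path(d2, "s"))
  write_dicom_slice(file.path(d2, "s", "a.dcm"), vol[, , 1], 1, "1.1")
  write_dicom_slice(file.path(d2, "s", "b.dcm"), vol[, , 2], 2, "9.9")
  expect_error(dicom_to_nifti(file.path(d2, "s")), "mixed series")
})

test_that("RAS reorientation permutes and flips as the axis codes dictate", {
  arr <- array(seq_len(3 * 4 * 5), dim = c(3, 4, 5))
  ras <- image_volume(arr, spacing = c(1, 2, 3), orientation = "RAS")
  expect_identical(reorient_to_ras(ras), ras)

  lps <- image_volume(arr, spacing = c(1, 2, 3), orientation = "LPS")
  out <- reorient_to_ras(lps)
  expect_identical(out$orientation, "RAS")
  # brute-force index map: L->R and P->A are flips of axes 1 and 2
  ref <- arr[3:1, 4:1, , drop = FALSE]
  expect_identical(out$voxels, ref)
  expect_identical(reorient_to_ras(out), out)  # idempotent
  expect_identical(sort(as.vector(out$voxels)), sort(as.vector(arr)))

  # axis permutation: ASR means (axis1 = A, axis2 = S, axis3 = R)
  asr <- image_volume(arr, spacing = c(1, 2, 3), orientation = "ASR")
  out2 <- reorient_to_ras(asr)
  expect_identical(dim(out2$voxels), c(5L, 3L, 4L))
  expect_identical(out2$spacing, c(3, 1, 2))
  # voxel at (x=1,y=2,z=3) in ASR shows up at (r=3, a=1, s=2)
  expect_identical(out2$voxels[3, 1, 2], arr[1, 2, 3])
  expect_error(image_volume(arr, orientation = "RAQ"), "orientation")
  expect_error(image_volume(arr, orientation = "RRS"), "axis pair")
})

test_that("volumes survive a NIfTI write/read round trip", {
  d <- withr::local_tempdir()
  vol <- image_volume(array(rnorm(4 * 5 * 6), dim = c(4, 5, 6)),
                      spacing = c(0.5, 1, 2), patient_id = "p1")
  p <- file.path(d, "v.nii.gz")
  write_volume(vol, p)
  back <- read_volume(p, patient_id = "p1")
  expect_equal(back$voxels, vol$voxels, tolerance = 1e-6)
  expect_equal(back$spacing, vol$spacing)
})

test_that("subtraction is clamped at zero and antitone in PC", {
  a <- array(c(3, 5, 2, 8), dim = c(2, 2, 1))
  b <- array(c(5, 1, 2, 4), dim = c(2, 2, 1))
  fpc <- image_volume(a, role = "FPC", patient_id = "p")
  pc <- image_volume(b, role = "PC", patient_id = "p")
  s <- subtract(fpc, pc)
  expect_identical(s$role, "SUBTRACTION")
  expect_equal(s$voxels, array(c(0, 4, 0, 4), dim = c(2, 2, 1)))

  expect_equal(subtract(fpc, fpc)$voxels, array(0, dim = c(2, 2, 1)))

  set.seed(1)
  x <- array(rnorm(60), dim = c(3, 4, 5))
  y <- array(rnorm(60), dim = c(3, 4, 5))
  s2 <- subtract(image_volume(x, role = "FPC"), image_volume(y))
  expect_equal(s2$voxels, pmax(x - y, 0))
  # raising any PC voxel never raises the subtraction voxel
  y2 <- y; y2[2, 2, 2] <- y2[2, 2, 2] + 1
  s3 <- subtract(image_volume(x, role = "FPC"), image_volume(y2))
  expect_true(all(s3$voxels <= s2$voxels))

  pc2 <- image_volume(b, role = "PC", patient_id = "other")
  expect_error(subtract(fpc, pc2), "different patients")
  expect_error(subtract(fpc, image_volume(array(0, c(3, 3, 1)))),
               "alignment")
})

test_that("oversampling duplicates adjacent slices deterministically", {
  set.seed(2)
  vol <- image_volume(array(rnorm(4 * 4 * 24), dim = c(4, 4, 24)))
  expect_identical(oversample_to_depth(vol, 24, seed = 1), vol)
  out <- oversample_to_depth(vol, 42, seed = 9)
  expect_identical(dim(out$voxels)[3], 42L)
  # every output slice equals some input slice (slice-hash membership)
  in_hashes <- apply(vol$voxels, 3, function(s) paste(s, collapse = ","))
  out_hashes <- apply(out$voxels, 3, function(s) paste(s, collapse = ","))
  expect_true(all(out_hashes %in% in_hashes))
  # order preserved: source index sequence is non-decreasing
  src <- match(out_hashes, in_hashes)
  expect_true(all(diff(src) >= 0))
  # determinism and image/mask pairing under a shared seed
  expect_identical(oversample_to_depth(vol, 42, seed = 9), out)
  msk <- rand_mask(c(4, 4, 24), seed = 3)
  om <- oversample_to_depth(msk, 42, seed = 9)
  idx <- ovseg:::oversample_indices(24, 42, 9)
  expect_identical(om$voxels, msk$voxels[, , idx])
  expect_identical(out$voxels, vol$voxels[, , idx])  # same seed, same slices
  expect_error(oversample_to_depth(vol, 10, seed = 1), "contract error")
})
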