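# Shared fixtures, all generated in code at test time.

# standard small phantom cohort, built once per test run
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(phantom_config(
        n_patients = 4L, volume_shape = c(96L, 96L, 24L),
        artifact_slices = 2L, seed = 7L))
    cache
  }
})

make_image <- function(arr, ...) image_volume(arr, ...)

rand_mask <- function(dim3, p = 0.1, seed = 1) {
  set.seed(seed)
  mask_volume(array(as.integer(stats::runif(prod(dim3)) < p), dim = dim3))
}

# ---- minimal explicit-VR little-endian DICOM writer (test fixture) ----

dcm_elem_short <- function(con, group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, charToRaw(" "))
  writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
  writeChar(vr, con, eos = NULL)
  writeBin(length(value_raw), con, size = 2, endian = "little")
  writeBin(value_raw, con)
}

dcm_elem_long <- function(con, group, elem, vr, value_raw) {
  writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
  writeChar(vr, con, eos = NULL)
  writeBin(as.integer(0), con, size = 2, endian = "little")  # reserved
  writeBin(length(value_raw), con, size = 4, endian = "little")
  writeBin(value_raw, con)
}

us_raw <- function(x) writeBin(as.integer(x), raw(), size = 2,
                               endian = "little")

write_dicom_slice <- function(path, mat, instance, uid,
                              desc = "T1 PRE", acq_time = "120000",
                              pos = c(0, 0, instance),
                              pixel_spacing = c(1, 1)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  dcm_elem_short(con, 0x0008, 0x0032, "TM", charToRaw(acq_time))
  dcm_elem_short(con, 0x0008, 0x103e, "LO", charToRaw(desc))
  dcm_elem_short(con, 0x0020, 0x000e, "UI", charToRaw(uid))
  dcm_elem_short(con, 0x0020, 0x0013, "IS", charToRaw(as.character(instance)))
  dcm_elem_short(con, 0x0020, 0x0032, "DS",
                 charToRaw(paste(pos, collapse = "\\")))
  dcm_elem_short(con, 0x0028, 0x0010, "US", us_raw(nrow(mat)))
  dcm_elem_short(con, 0x0028, 0x0011, "US", us_raw(ncol(mat)))
  dcm_elem_short(con, 0x0028, 0x0030, "DS",
                 charToRaw(paste(pixel_spacing, collapse = "\\")))
  dcm_elem_short(con, 0x0028, 0x0100, "US", us_raw(16))
  dcm_elem_short(con, 0x0028, 0x0103, "US", us_raw(1))
  v <- as.vector(t(mat))  # row-major pixel order
  dcm_elem_long(con, 0x7fe0, 0x0010, "OW",
                writeBin(as.integer(v), raw(), size = 2, endian = "little"))
  invisible(path)
}

write_dicom_series <- function(dir, vol, uid = "1.2.3.4", desc = "T1 PRE",
                               acq_time = "120000", instances = NULL,
                               pixel_spacing = c(1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  z <- dim(vol)[3]
  if (is.null(instances)) instances <- seq_len(z)
  for (k in seq_len(z))
    write_dicom_slice(file.path(dir, sprintf("slice%03d.dcm", k)),
                      vol[, , k], instances[k], uid, desc, acq_time,
                      pos = c(0, 0, k - 1), pixel_spacing = pixel_spacing)
  invisible(dir)
}
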