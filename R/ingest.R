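# Series discovery, DICOM ingest, RAS reorientation, subtraction images and
# random oversampling to a harmonized depth.

#' Discover PC/FPC series for one patient
#'
#' Scans a patient directory for pre-contrast and first post-contrast series,
#' identified by filename convention (`fpc`/`post` vs `pc`/`pre`), DICOM
#' series-description keywords, or acquisition-time ordering as a last
#' resort. Missing series never raise: the returned stub is flagged
#' incomplete with a reason, mirroring the cohort exclusion semantics.
#'
#' @param patient_dir Directory containing NIfTI files or DICOM series
#'   subdirectories for one patient.
#' @return A [patient_record()] stub with `complete`, `incomplete_reason` and
#'   a `source_paths` list naming the PC and FPC locations found.
#' @export
discover_series <- function(patient_dir) {
  if (!dir.exists(patient_dir))
    stop("I/O error: cannot read directory ", patient_dir)
  entries <- list.files(patient_dir, full.names = TRUE)
  paths <- list(pc = NULL, fpc = NULL)
  unclassified <- character(0)

  classify_name <- function(name) {
    if (grepl("fpc|post", name, ignore.case = TRUE)) return("fpc")
    if (grepl("(^|[^f])pc|pre", name, ignore.case = TRUE)) return("pc")
    NA_character_
  }

  for (p in entries) {
    is_series <- dir.exists(p) || grepl("\\.nii(\\.gz)?$|\\.dcm$", p)
    if (!is_series) next
    cls <- classify_name(basename(p))
    if (is.na(cls) && dir.exists(p)) {
      desc <- tryCatch(dicom_series_description(p), error = function(e) "")
      cls <- classify_name(desc)
      if (!is.na(cls)) message("classified ", basename(p),
                               " from DICOM series description")
    }
    if (is.na(cls)) unclassified <- c(unclassified, p)
    else if (is.null(paths[[cls]])) paths[[cls]] <- p
  }

  if ((is.null(paths$pc) || is.null(paths$fpc)) &&
      length(unclassified) == 2 && all(dir.exists(unclassified))) {
    times <- vapply(unclassified, function(p)
      tryCatch(dicom_series_time(p), error = function(e) NA_real_),
      numeric(1))
    if (!anyNA(times)) {
      ord <- order(times)
      paths$pc <- unclassified[ord[1]]
      paths$fpc <- unclassified[ord[2]]
      message("classified series by acquisition-time ordering")
    }
  }

  missing <- c(if (is.null(paths$pc)) "missing PC",
               if (is.null(paths$fpc)) "missing FPC")
  rec <- patient_record(patient_id = basename(patient_dir),
                        complete = length(missing) == 0,
                        incomplete_reason =
                          if (length(missing)) paste(missing, collapse = ", "))
  rec$source_paths <- paths
  rec
}

# ---- minimal single-frame DICOM (explicit VR, little endian) ----

dicom_read_element <- function(con) {
  hdr <- readBin(con, "raw", 4)
  if (length(hdr) < 4) return(NULL)
  group <- readBin(hdr[1:2], "integer", size = 2, signed = FALSE,
                   endian = "little")
  elem <- readBin(hdr[3:4], "integer", size = 2, signed = FALSE,
                  endian = "little")
  vr <- rawToChar(readBin(con, "raw", 2))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    readBin(con, "raw", 2)  # reserved
    len <- readBin(con, "integer", size = 4, endian = "little")
  } else {
    len <- readBin(con, "integer", size = 2, signed = FALSE,
                   endian = "little")
  }
  if (len < 0) stop("format error: undefined-length element unsupported")
  value <- readBin(con, "raw", len)
  list(group = group, elem = elem, vr = vr, value = value)
}

dicom_parse_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132)
  if (length(preamble) < 132 || rawToChar(preamble[129:132]) != "DICM")
    stop("format error: ", path, " lacks the DICM magic marker")
  tags <- list()
  repeat {
    el <- dicom_read_element(con)
    if (is.null(el)) break
    key <- sprintf("%04x,%04x", el$group, el$elem)
    tags[[key]] <- el
    if (el$group == 0x7fe0 && el$elem == 0x0010) break
  }
  tags
}

dicom_string <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NA_character_)
  trimws(rawToChar(el$value))
}

dicom_numbers <- function(tags, key) {
  s <- dicom_string(tags, key)
  if (is.na(s)) return(NA_real_)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_us <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NA_integer_)
  readBin(el$value, "integer", size = 2, signed = FALSE, endian = "little")
}

dicom_series_description <- function(series_dir) {
  f <- list.files(series_dir, pattern = "\\.dcm$", full.names = TRUE)[1]
  if (is.na(f)) stop("format error: no DICOM files in ", series_dir)
  dicom_string(dicom_parse_file(f), "0008,103e")
}

dicom_series_time <- function(series_dir) {
  f <- list.files(series_dir, pattern = "\\.dcm$", full.names = TRUE)[1]
  if (is.na(f)) stop("format error: no DICOM files in ", series_dir)
  as.numeric(dicom_string(dicom_parse_file(f), "0008,0032"))
}

#' Read a single-frame DICOM series as a volume
#'
#' Minimal reader for explicit-VR little-endian, single-frame MR series:
#' slices are assembled in instance-number order, geometry comes from the
#' pixel-spacing and image-position tags, and inconsistent series (mixed
#' UIDs, varying spacing or a gap in instance numbers) raise a format error.
#'
#' @param series_dir Directory of `.dcm` files forming one series.
#' @param role Series role for the result.
#' @param patient_id Patient identifier to attach.
#' @return An [image_volume()].
#' @export
dicom_to_nifti <- function(series_dir, role = "PC", patient_id = "unknown") {
  files <- list.files(series_dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0)
    stop("format error: no DICOM files in ", series_dir)
  parsed <- lapply(files, dicom_parse_file)

  uids <- vapply(parsed, dicom_string, character(1), key = "0020,000e")
  if (length(unique(uids)) != 1)
    stop("format error: mixed series instance UIDs in ", series_dir)

  inst <- vapply(parsed, function(t)
    as.integer(dicom_string(t, "0020,0013")), integer(1))
  ord <- order(inst)
  parsed <- parsed[ord]
  inst <- inst[ord]
  if (!all(diff(inst) == 1L))
    stop("format error: missing instance number in series (have ",
         paste(inst, collapse = ","), ")")

  rows <- vapply(parsed, dicom_us, integer(1), key = "0028,0010")
  cols <- vapply(parsed, dicom_us, integer(1), key = "0028,0011")
  psp <- t(vapply(parsed, dicom_numbers, numeric(2), key = "0028,0030"))
  if (length(unique(rows)) != 1 || length(unique(cols)) != 1 ||
      nrow(unique(psp)) != 1)
    stop("format error: inconsistent slice geometry in ", series_dir)

  nx <- rows[1]; ny <- cols[1]
  slices <- lapply(parsed, function(t) {
    el <- t[["7fe0,0010"]]
    if (is.null(el)) stop("format error: slice without pixel data")
    signed <- isTRUE(dicom_us(t, "0028,0103") == 1L)
    v <- readBin(el$value, "integer", n = nx * ny, size = 2,
                 signed = signed, endian = "little")
    t(matrix(v, nrow = ny, ncol = nx))  # row-major pixel order -> [x, y]
  })
  vol <- array(0, dim = c(nx, ny, length(slices)))
  for (k in seq_along(slices)) vol[, , k] <- slices[[k]]

  zsp <- 1
  pos <- t(vapply(parsed, dicom_numbers, numeric(3), key = "0020,0032"))
  if (!anyNA(pos) && nrow(pos) > 1)
    zsp <- sqrt(sum((pos[2, ] - pos[1, ])^2))
  image_volume(vol, spacing = c(psp[1, 1], psp[1, 2], max(zsp, 1e-6)),
               role = role, patient_id = patient_id)
}

# ---- RAS reorientation ----

#' Reorient a volume to RAS
#'
#' Permutes and flips the voxel grid (and spacing) so that the orientation
#' code becomes `"RAS"`. Idempotent; the multiset of voxel values is
#' preserved.
#'
#' @param vol An [image_volume()] or [mask_volume()].
#' @return The reoriented volume.
#' @export
reorient_to_ras <- function(vol) {
  pairs <- check_orientation(vol$orientation)  # pair index per source axis
  target <- c("R", "A", "S")
  letters3 <- strsplit(vol$orientation, "")[[1]]
  perm <- integer(3)
  flip <- logical(3)
  for (t_axis in 1:3) {
    s_axis <- which(pairs == t_axis)
    perm[t_axis] <- s_axis
    flip[t_axis] <- letters3[s_axis] != target[t_axis]
  }
  v <- aperm(vol$voxels, perm)
  idx <- lapply(1:3, function(a) if (flip[a]) rev(seq_len(dim(v)[a]))
                else seq_len(dim(v)[a]))
  v <- v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  vol$voxels <- v
  vol$spacing <- vol$spacing[perm]
  vol$orientation <- "RAS"
  vol
}

#' Subtraction image
#'
#' Voxel-wise `FPC - PC`, clamped at zero: negative differences carry no
#' enhancement signal. Requires identical geometry and patient.
#'
#' @param fpc,pc [image_volume()] objects for the same patient.
#' @return An [image_volume()] with role `"SUBTRACTION"`.
#' @export
subtract <- function(fpc, pc) {
  stop_if_geometry_mismatch(fpc, pc, "FPC and PC")
  if (!identical(fpc$patient_id, pc$patient_id))
    stop("alignment error: FPC and PC belong to different patients")
  image_volume(pmax(fpc$voxels - pc$voxels, 0), spacing = fpc$spacing,
               orientation = fpc$orientation, role = "SUBTRACTION",
               patient_id = fpc$patient_id)
}

# Slice index multiplicities realizing a seeded random oversampling: each
# duplicate is placed adjacent to its source slice, order preserved.
oversample_indices <- function(z, target_z, seed) {
  if (target_z < z)
    stop("contract error: target depth ", target_z, " is below current ", z,
         " (downsampling is not oversampling)")
  if (z < 1) stop("contract error: empty volume")
  if (target_z == z) return(seq_len(z))
  extra <- with_preserved_rng({
    set.seed(seed)
    sample.int(z, target_z - z, replace = TRUE)
  })
  counts <- tabulate(extra, nbins = z) + 1L
  rep(seq_len(z), times = counts)
}

#' Oversample a volume to a target depth
#'
#' Random oversampling along z: inserted slices are copies of randomly chosen
#' existing slices placed adjacent to their source, preserving slice order.
#' Paired image and mask volumes oversampled with the same seed stay aligned.
#'
#' @param vol An [image_volume()] or [mask_volume()].
#' @param target_z Desired depth, `>=` the current depth.
#' @param seed Integer seed; the operation is deterministic given it.
#' @return The deepened volume.
#' @export
oversample_to_depth <- function(vol, target_z, seed) {
  idx <- oversample_indices(dim(vol$voxels)[3], target_z, seed)
  vol$voxels <- vol$voxels[, , idx, drop = FALSE]
  vol
}
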