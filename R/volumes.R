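#' @useDynLib ovseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Project-wide axis convention (standard RAS NIfTI layout): array axis 1 =
# left -> right (R), axis 2 = anterior -> posterior in index direction (the
# "x" axis of the crop/overlay API, the axis the optimal-volume crop
# shortens, 352 -> 192), axis 3 = slice index (S). Indices are 1-based
# inclusive; spans (last - first + 1) equal any 0-based reading.

#' Construct an image volume
#'
#' A 3D scalar volume with voxel spacing, an anatomical orientation code and a
#' series role. This is the basic container passed between all pipeline
#' stages.
#'
#' @param voxels 3D numeric array `(X, Y, Z)`.
#' @param spacing Numeric length-3, mm per axis; strictly positive.
#' @param orientation Three-letter axis code (one letter per array axis, each
#'   from one of the pairs R/L, A/P, S/I), giving the anatomical direction of
#'   increasing index. The package's canonical code is `"RAS"`.
#' @param role One of `"PC"`, `"FPC"`, `"SUBTRACTION"`, `"MASK"`.
#' @param patient_id Character scalar.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), orientation = "RAS",
                         role = c("PC", "FPC", "SUBTRACTION", "MASK"),
                         patient_id = "unknown") {
  role <- match.arg(role)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  check_orientation(orientation)
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         orientation = orientation, role = role,
         patient_id = as.character(patient_id)),
    class = "image_volume"
  )
}

#' Construct a binary mask volume
#'
#' A `{0,1}`-valued 3D volume housing per-slice binary masks (breast region,
#' lesion annotation or model prediction).
#'
#' @param voxels 3D array with values exactly 0 or 1 (logical accepted).
#' @param spacing,orientation,patient_id As in [image_volume()].
#' @param kind One of `"REGION"`, `"LESION"`, `"PREDICTION"`.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(voxels, spacing = c(1, 1, 1), orientation = "RAS",
                        kind = c("REGION", "LESION", "PREDICTION"),
                        patient_id = "unknown") {
  kind <- match.arg(kind)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (is.logical(voxels)) {
    voxels <- array(as.integer(voxels), dim = dim(voxels))
  }
  if (!all(voxels %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  check_orientation(orientation)
  structure(
    list(voxels = array(as.integer(voxels), dim = dim(voxels)),
         spacing = as.numeric(spacing), orientation = orientation,
         kind = kind, patient_id = as.character(patient_id)),
    class = "mask_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s %s [%s] spacing %s mm, orientation %s\n",
              x$patient_id, x$role, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"), x$orientation))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s %s [%s] %d foreground voxels\n",
              x$patient_id, x$kind, paste(dim(x$voxels), collapse = "x"),
              sum(x$voxels)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

#' @export
dim.mask_volume <- function(x) dim(x$voxels)

valid_axis_letters <- list(c("R", "L"), c("A", "P"), c("S", "I"))

check_orientation <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 3L)
    stop("orientation must be a 3-letter axis code, e.g. \"RAS\"")
  letters3 <- strsplit(code, "")[[1]]
  pair_of <- function(l) which(vapply(valid_axis_letters,
                                      function(p) l %in% p, logical(1)))
  pairs <- vapply(letters3, function(l) {
    p <- pair_of(l)
    if (length(p) != 1L) stop("unknown orientation letter: ", l)
    p
  }, integer(1))
  if (length(unique(pairs)) != 3L)
    stop("orientation code must use each anatomical axis pair exactly once: ",
         code)
  invisible(pairs)
}

same_geometry <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    identical(a$orientation, b$orientation)
}

stop_if_geometry_mismatch <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    stop("alignment error: ", what, " differ in shape, spacing or orientation")
  invisible(TRUE)
}

# RAS affine for the canonical layout: diagonal, positive spacing.
ras_affine <- function(spacing) {
  aff <- diag(c(spacing, 1))
  storage.mode(aff) <- "double"
  aff
}

#' Write a volume to NIfTI
#'
#' Images are stored as float32, masks as uint8, both with an RAS-positive
#' diagonal affine built from the voxel spacing.
#'
#' @param vol An [image_volume()] or [mask_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  is_mask <- inherits(vol, "mask_volume")
  dat <- vol$voxels
  storage.mode(dat) <- if (is_mask) "integer" else "double"
  img <- RNifti::asNifti(structure(dat, pixdim = vol$spacing),
                         datatype = if (is_mask) "uint8" else "float")
  RNifti::sform(img) <- structure(ras_affine(vol$spacing), code = 2L)
  RNifti::qform(img) <- structure(ras_affine(vol$spacing), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file path.
#' @param role Series role for the returned [image_volume()].
#' @param as_mask Read as a [mask_volume()] of the given `kind` instead.
#' @param kind Mask kind when `as_mask = TRUE`.
#' @param patient_id Patient identifier to attach.
#' @return An `image_volume` or `mask_volume`.
#' @export
read_volume <- function(path, role = "PC", as_mask = FALSE, kind = "REGION",
                        patient_id = "unknown") {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (as_mask) {
    mask_volume(array(as.integer(arr != 0), dim = dim(arr)), spacing = sp,
                kind = kind, patient_id = patient_id)
  } else {
    image_volume(arr, spacing = sp, role = role, patient_id = patient_id)
  }
}
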