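# Breast-region masks: a classical heuristic stand-in for a pretrained
# whole-breast segmentation model, plus mask application.

#' Morphological cleanup of a binary volume
#'
#' Opening followed by closing with a spherical structuring element.
#'
#' @param voxels 3D integer `{0,1}` array.
#' @param radius Ball radius in voxels.
#' @return Cleaned `{0,1}` array of the same shape.
#' @export
morph_cleanup <- function(voxels, radius = 3) {
  d <- dim(voxels)
  v <- as.integer(voxels)
  v <- .bin_dilate(.bin_erode(v, d, radius), d, radius)   # opening
  v <- .bin_erode(.bin_dilate(v, d, radius), d, radius)   # closing
  array(v, dim = d)
}

#' Heuristic breast-region segmentation
#'
#' Stand-in for a learned whole-breast segmentation model: global Otsu
#' threshold on the pre-contrast volume, morphological opening/closing with a
#' 3-voxel ball, then retention of the (up to) two largest connected
#' components whose centroids lie anterior to the volume's x midpoint.
#' Foreground is restricted to the anterior half of the x axis plus a
#' configurable posterior margin. Externally supplied masks (including the
#' phantom ground truth) pass through the same interface downstream.
#'
#' @param pc Pre-contrast [image_volume()] in the canonical RAS layout.
#' @param posterior_margin Extra voxels beyond the x midpoint kept as
#'   candidate foreground.
#' @param cleanup_radius Structuring-element radius in voxels.
#' @return A [mask_volume()] of kind `"REGION"`. An all-zero input yields an
#'   all-zero mask carrying attribute `empty_input = TRUE` (with a warning).
#' @export
predict_breast_mask <- function(pc, posterior_margin = 0L,
                                cleanup_radius = 3) {
  vox <- pc$voxels
  d <- dim(vox)
  if (all(vox == 0)) {
    warning("all-zero image: returning an empty breast-region mask")
    out <- mask_volume(array(0L, dim = d), spacing = pc$spacing,
                       orientation = pc$orientation, kind = "REGION",
                       patient_id = pc$patient_id)
    attr(out, "empty_input") <- TRUE
    return(out)
  }
  rng <- range(vox)
  norm <- (vox - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(matrix(norm, nrow = d[1])))
  bin <- array(as.integer(norm > thr), dim = d)

  # candidate region: anterior half (low ap index) plus margin
  ap_limit <- d[2] %/% 2L + as.integer(posterior_margin)
  bin[, seq_len(d[2]) > ap_limit, ] <- 0L

  # iterate the cleanup to a fixed point (converges in 1-2 passes)
  for (pass in 1:5) {
    nxt <- morph_cleanup(bin, cleanup_radius)
    if (identical(nxt, bin)) break
    bin <- nxt
  }

  labels <- .cc_label_26(as.integer(bin), d)
  k <- attr(labels, "n_components")
  if (k > 0) {
    labels <- array(labels, dim = d)
    sizes <- tabulate(labels[labels > 0], nbins = k)
    cent_ap <- vapply(seq_len(k), function(l) {
      mean(which(labels == l, arr.ind = TRUE)[, 2])
    }, numeric(1))
    anterior <- which(cent_ap <= d[2] / 2 + posterior_margin)
    keep <- anterior[order(sizes[anterior], decreasing = TRUE)]
    keep <- keep[seq_len(min(2L, length(keep)))]
    bin <- array(as.integer(labels %in% keep), dim = d)
  }
  mask_volume(bin, spacing = pc$spacing, orientation = pc$orientation,
              kind = "REGION", patient_id = pc$patient_id)
}

#' Apply a binary mask to an image
#'
#' Voxel-wise product: voxels outside the mask become exactly zero, removing
#' low-intensity anterior noise and posterior organs (heart, lungs) from the
#' series. Idempotent for a fixed mask.
#'
#' @param img An [image_volume()].
#' @param mask A [mask_volume()] with matching geometry.
#' @return The masked [image_volume()].
#' @export
apply_mask <- function(img, mask) {
  stop_if_geometry_mismatch(img, mask, "image and mask")
  img$voxels <- img$voxels * mask$voxels
  img
}
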