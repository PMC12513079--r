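# Annotation-density overlay maps: pixel-wise sums of binary masks across
# all patients and slices, plus the axis-histogram and midline-span
# analytics derived from them.

#' Aggregate binary masks into an overlay map
#'
#' `grid(lr, ap) = sum over patients p, slices s of M_{p,s}(lr, ap)`: the
#' per-pixel count of mask foreground across the whole cohort. The grid sum
#' equals the total foreground voxel count of the inputs, and no cell can
#' exceed the total slice count.
#'
#' @param masks List of [mask_volume()]s sharing the in-plane shape.
#' @return An `overlay_map` with fields `grid` (integer matrix, LR x AP),
#'   `n_patients`, `n_slices_total` and `source_kind`.
#' @export
overlay_map <- function(masks) {
  stopifnot(length(masks) > 0)
  shp <- dim(masks[[1]]$voxels)[1:2]
  grid <- matrix(0L, nrow = shp[1], ncol = shp[2])
  n_slices <- 0L
  for (m in masks) {
    d <- dim(m$voxels)
    if (!identical(d[1:2], shp))
      stop("alignment error: mask in-plane shapes differ")
    grid <- grid + rowSums(m$voxels, dims = 2)
    n_slices <- n_slices + d[3]
  }
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, n_patients = length(masks),
                 n_slices_total = n_slices,
                 source_kind = masks[[1]]$kind),
            class = "overlay_map")
}

#' @export
print.overlay_map <- function(x, ...) {
  cat(sprintf("<overlay_map> %s: %dx%d grid, %d patients, %d slices, max %d\n",
              x$source_kind, nrow(x$grid), ncol(x$grid), x$n_patients,
              x$n_slices_total, max(x$grid)))
  invisible(x)
}

#' Marginal histogram of an overlay map
#'
#' Sums the overlay grid along the other axis: `axis = "x"` gives the
#' profile along the anterior-posterior axis, `axis = "y"` along the
#' left-right axis. Both profiles share the grid total.
#'
#' @param map An [overlay_map()].
#' @param axis `"x"` (anterior-posterior) or `"y"` (left-right).
#' @return Numeric profile vector.
#' @export
axis_histogram <- function(map, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") colSums(map$grid) else rowSums(map$grid)
}

#' Midline profile and span
#'
#' Extracts the overlay row at the body midline (left-right index
#' `floor(LR/2) + 1`) and measures the contiguous extent of its non-zero
#' support along the anterior-posterior axis:
#' `h_max_mid = last non-zero - first non-zero + 1` (0 for an empty row).
#' The span measure (not the non-zero count) is used so that the crop
#' arithmetic `extent + safe distance -> multiple of 32` is consistent.
#'
#' @param map An [overlay_map()].
#' @return A `midline_profile` with `values` and `h_max_mid`.
#' @export
midline_span <- function(map) {
  mid <- nrow(map$grid) %/% 2L + 1L
  values <- map$grid[mid, ]
  nz <- which(values != 0)
  h <- if (length(nz) == 0) 0L else as.integer(max(nz) - min(nz) + 1L)
  structure(list(values = values, h_max_mid = h), class = "midline_profile")
}

#' @export
print.midline_profile <- function(x, ...) {
  cat(sprintf("<midline_profile> length %d, h_max_mid = %d\n",
              length(x$values), x$h_max_mid))
  invisible(x)
}

#' Write overlay products to disk
#'
#' The grid as a 2D NIfTI and a PNG heat map with a colorbar, plus the two
#' axis histograms as CSV.
#'
#' @param map An [overlay_map()].
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_overlay <- function(map, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  nii <- paste0(prefix, "_overlay.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(map$grid * 1.0), nii)
  png_path <- paste0(prefix, "_overlay.png")
  grDevices::png(png_path, width = 720, height = 600)
  old <- graphics::par(no.readonly = TRUE)
  on.exit({ graphics::par(old); grDevices::dev.off() }, add = TRUE)
  graphics::layout(matrix(1:2, nrow = 1), widths = c(5, 1))
  pal <- grDevices::hcl.colors(64, "inferno")
  zmax <- max(map$grid, 1L)
  graphics::image(seq_len(nrow(map$grid)), seq_len(ncol(map$grid)),
                  map$grid, zlim = c(0, zmax), col = pal,
                  xlab = "left-right", ylab = "anterior-posterior",
                  main = paste(map$source_kind, "overlay"),
                  useRaster = TRUE)
  graphics::par(mar = c(5, 1, 4, 3))
  graphics::image(1, seq(0, zmax, length.out = 64),
                  matrix(seq(0, zmax, length.out = 64), nrow = 1),
                  col = pal, xaxt = "n", xlab = "", ylab = "")
  csv <- paste0(prefix, "_histograms.csv")
  hx <- axis_histogram(map, "x")
  hy <- axis_histogram(map, "y")
  n <- max(length(hx), length(hy))
  utils::write.csv(data.frame(index = seq_len(n),
                              x_profile = c(hx, rep(NA, n - length(hx))),
                              y_profile = c(hy, rep(NA, n - length(hy)))),
                   csv, row.names = FALSE)
  invisible(c(nii, png_path, csv))
}
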