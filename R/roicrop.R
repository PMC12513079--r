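# Slice/height optimization: measure breast extents on BRS-masked volumes,
# derive the cohort-wide optimal-volume (OV) crop, and build the four dataset
# variants (WV, BRS_WV, BRS_SLS, BRS_OV).

VARIANTS <- c("WV", "BRS_WV", "BRS_SLS", "BRS_OV")

#' Anterior-posterior extent of the non-zero support
#'
#' Scans all slices for the first and last non-zero x coordinate (1-based,
#' inclusive): the minimal interval along the anterior-posterior axis that
#' contains every non-zero voxel.
#'
#' @param masked An [image_volume()] or [mask_volume()].
#' @return Integer `c(x_first, x_last)` along the anterior-posterior axis
#'   (array dimension 2).
#' @export
vertical_extent <- function(masked) {
  support <- colSums(masked$voxels != 0)        # (AP, Z) counts
  nz <- which(rowSums(support) > 0)
  if (length(nz) == 0)
    stop("empty-extent error: volume of patient ", masked$patient_id,
         " is all zero")
  c(x_first = min(nz), x_last = max(nz))
}

#' Maximum breast depth along the body midline
#'
#' At the body-midline left-right index `floor(LR/2) + 1`, the span
#' `x_last - x_first + 1` of non-zero voxels, maximized over slices. Returns
#' 0 with a warning when the midline column is empty on every slice.
#'
#' @param region A breast-region [mask_volume()].
#' @return Depth in voxels.
#' @export
midline_depth <- function(region) {
  d <- dim(region$voxels)
  mid_lr <- d[1] %/% 2L + 1L
  col <- region$voxels[mid_lr, , , drop = FALSE]  # (1, AP, Z)
  spans <- vapply(seq_len(d[3]), function(z) {
    nz <- which(col[1, , z] != 0)
    if (length(nz) == 0) 0L else max(nz) - min(nz) + 1L
  }, integer(1))
  if (all(spans == 0L)) {
    warning("midline column empty on every slice for patient ",
            region$patient_id)
    return(0L)
  }
  max(spans)
}

#' Cohort crop height
#'
#' The smallest multiple of `divisor` that is at least
#' `max_extent + safe_distance`: the optimal-volume height rule (a measured
#' maximal midline extent of 176 px with a 16-px safe distance and divisor 32
#' yields 192 px).
#'
#' @param max_extent Maximal measured breast extent, voxels (> 0).
#' @param safe_distance Safety margin in voxels (>= 0).
#' @param divisor Divisibility constraint, default 32.
#' @param volume_x Optional volume height; exceeding it raises an error
#'   instructing to reduce the safe distance.
#' @return Crop height in voxels, a multiple of `divisor`.
#' @export
cohort_crop_height <- function(max_extent, safe_distance = 16L,
                               divisor = 32L, volume_x = NULL) {
  if (max_extent <= 0 || divisor <= 0 || safe_distance < 0)
    stop("cohort_crop_height: `max_extent` and `divisor` must be positive, ",
         "`safe_distance` non-negative")
  h <- as.integer(ceiling((max_extent + safe_distance) / divisor) * divisor)
  if (!is.null(volume_x) && h > volume_x)
    stop("crop height ", h, " exceeds the volume height ", volume_x,
         ": reduce the safe distance")
  h
}

#' Slice range containing lesions
#'
#' First and last slice index (1-based, inclusive) with at least one lesion
#' voxel, or `NULL` when the mask is empty (the patient is then excluded
#' from the SLS/OV variants).
#'
#' @param lesions A lesion [mask_volume()].
#' @return Integer `c(z_first, z_last)` or `NULL`.
#' @export
lesion_slice_range <- function(lesions) {
  per_slice <- colSums(matrix(lesions$voxels,
                              ncol = dim(lesions$voxels)[3]))
  nz <- which(per_slice > 0)
  if (length(nz) == 0) return(NULL)
  c(z_first = min(nz), z_last = max(nz))
}

#' Harmonize lesion slabs across a cohort
#'
#' The shared slab depth is the maximal per-patient lesion span; each
#' patient's slab is centred on the midpoint of its lesion range and clamped
#' to the volume, so every lesion slice lies inside its slab. Patients
#' shallower than the slab are flagged for oversampling.
#'
#' @param ranges Named list of per-patient `c(z_first, z_last)`.
#' @param depths Named integer vector of per-patient volume depths.
#' @return List with `slab_size`, named `z_starts`, and a logical
#'   `needs_oversample` per patient.
#' @export
harmonize_slab <- function(ranges, depths) {
  if (length(ranges) == 0) stop("harmonize_slab: no patients")
  spans <- vapply(ranges, function(r) r[2] - r[1] + 1L, numeric(1))
  slab <- as.integer(max(spans))
  ids <- names(ranges)
  z_starts <- stats::setNames(integer(length(ranges)), ids)
  needs <- stats::setNames(logical(length(ranges)), ids)
  for (id in ids) {
    z <- as.integer(depths[[id]])
    if (z < slab) {
      needs[id] <- TRUE
      z_starts[id] <- 1L
      next
    }
    mid <- (ranges[[id]][1] + ranges[[id]][2]) / 2
    zs <- as.integer(round(mid - (slab - 1) / 2))
    z_starts[id] <- min(max(zs, 1L), z - slab + 1L)
  }
  list(slab_size = slab, z_starts = z_starts, needs_oversample = needs)
}

#' Crop specification for the optimal volume
#'
#' @param x_start First retained x index (1-based).
#' @param x_size Crop height, a multiple of `divisor`.
#' @param z_size Harmonized slab depth.
#' @param z_starts Named per-patient first slab slice.
#' @param safe_distance Safety margin used to derive `x_size`.
#' @param divisor Divisibility constraint.
#' @return A `crop_spec`.
#' @export
crop_spec <- function(x_start, x_size, z_size = NULL, z_starts = NULL,
                      safe_distance = 16L, divisor = 32L) {
  if (x_size %% divisor != 0)
    stop("crop_spec: `x_size` must be a multiple of ", divisor)
  if (x_size < 1 || x_start < 1 || (!is.null(z_size) && z_size < 1))
    stop("crop_spec: sizes must be >= 1 and `x_start` >= 1")
  if (safe_distance < 0) stop("crop_spec: `safe_distance` must be >= 0")
  structure(list(x_start = as.integer(x_start), x_size = as.integer(x_size),
                 z_size = if (!is.null(z_size)) as.integer(z_size),
                 z_starts = z_starts, safe_distance = as.integer(safe_distance),
                 divisor = as.integer(divisor)),
            class = "crop_spec")
}

# Region mask for a record under the chosen source.
record_region_mask <- function(rec, mask_source = c("groundtruth",
                                                    "heuristic")) {
  mask_source <- match.arg(mask_source)
  if (mask_source == "groundtruth") {
    if (is.null(rec$region_mask))
      stop("patient ", rec$patient_id, " has no ground-truth region mask")
    rec$region_mask
  } else {
    predict_breast_mask(rec$pc)
  }
}

#' Derive the cohort-wide OV crop from patient records
#'
#' Measures the anterior skin line (cohort minimum first non-zero x of the
#' BRS-masked pre-contrast volumes) and the maximal midline breast depth,
#' then applies the crop-height rule. Slab geometry comes from
#' [harmonize_slab()] over the per-patient lesion ranges; patients without
#' lesions are excluded.
#'
#' @param records List of complete [patient_record()]s.
#' @param safe_distance,divisor Crop-height rule parameters.
#' @param mask_source `"groundtruth"` or `"heuristic"` region masks.
#' @return A [crop_spec()] with attribute `excluded` listing lesion-free
#'   patients.
#' @export
compute_crop_spec <- function(records, safe_distance = 16L, divisor = 32L,
                              mask_source = "groundtruth") {
  stopifnot(length(records) > 0)
  regions <- lapply(records, record_region_mask, mask_source = mask_source)
  names(regions) <- vapply(records, `[[`, character(1), "patient_id")
  x_first <- min(vapply(seq_along(records), function(i) {
    masked <- apply_mask(records[[i]]$pc, regions[[i]])
    vertical_extent(masked)[1]
  }, numeric(1)))
  max_mid <- max(vapply(regions, midline_depth, numeric(1)))
  ap_size <- dim(records[[1]]$pc$voxels)[2]
  x_size <- cohort_crop_height(max_mid, safe_distance, divisor,
                               volume_x = ap_size)

  ranges <- list(); depths <- list(); excluded <- character(0)
  for (rec in records) {
    r <- lesion_slice_range(rec$lesion_mask)
    if (is.null(r)) excluded <- c(excluded, rec$patient_id)
    else {
      ranges[[rec$patient_id]] <- r
      depths[[rec$patient_id]] <- dim(rec$lesion_mask$voxels)[3]
    }
  }
  if (length(ranges) == 0)
    stop("no patient has lesion annotations; cannot derive a slab")
  slab <- harmonize_slab(ranges, depths)
  cs <- crop_spec(x_start = x_first, x_size = x_size,
                  z_size = slab$slab_size, z_starts = slab$z_starts,
                  safe_distance = safe_distance, divisor = divisor)
  attr(cs, "needs_oversample") <- slab$needs_oversample
  attr(cs, "excluded") <- excluded
  cs
}

# xs indexes the anterior-posterior axis (array dim 2), zs the slices.
crop_volume <- function(vol, xs = NULL, zs = NULL) {
  v <- vol$voxels
  if (!is.null(zs)) v <- v[, , zs, drop = FALSE]
  if (!is.null(xs)) v <- v[, xs, , drop = FALSE]
  vol$voxels <- v
  vol
}

#' Build a dataset variant
#'
#' Assembles one of the four datasets: `WV` (untouched whole volumes),
#' `BRS_WV` (region-masked whole volumes), `BRS_SLS` (region-masked volumes
#' restricted to the harmonized lesion slab) and `BRS_OV` (additionally
#' cropped along x to the optimal height). Labels undergo exactly the same
#' transforms. Any lesion voxel falling outside the OV crop is a hard error,
#' since the crop is designed to contain all lesions.
#'
#' @param records List of complete [patient_record()]s.
#' @param variant One of `"WV"`, `"BRS_WV"`, `"BRS_SLS"`, `"BRS_OV"`.
#' @param crop A [crop_spec()]; required for `BRS_SLS`/`BRS_OV` (computed via
#'   [compute_crop_spec()] when omitted).
#' @param mask_source Region-mask source for the BRS variants.
#' @param safe_distance,divisor Used only when `crop` must be computed.
#' @param oversample_seed Seed for joint image/label oversampling of patients
#'   shallower than the slab.
#' @return A `dataset_variant`: per-patient image stacks and labels, a shape
#'   record, the crop used and the excluded patient ids.
#' @export
build_variant <- function(records, variant = VARIANTS, crop = NULL,
                          mask_source = "groundtruth", safe_distance = 16L,
                          divisor = 32L, oversample_seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(all(vapply(records, `[[`, logical(1), "complete")))
  needs_crop <- variant %in% c("BRS_SLS", "BRS_OV")
  if (needs_crop && is.null(crop))
    crop <- compute_crop_spec(records, safe_distance, divisor, mask_source)
  excluded <- if (needs_crop) attr(crop, "excluded") else character(0)
  needs_os <- if (needs_crop) attr(crop, "needs_oversample") else NULL

  patients <- list()
  for (rec in records) {
    id <- rec$patient_id
    if (id %in% excluded) next
    imgs <- Filter(Negate(is.null),
                   rec[c("pc", "fpc", "subtraction")])
    label <- rec$lesion_mask
    if (variant != "WV") {
      region <- record_region_mask(rec, mask_source)
      imgs <- lapply(imgs, apply_mask, mask = region)
    }
    if (needs_crop) {
      z <- dim(label$voxels)[3]
      if (isTRUE(needs_os[[id]])) {
        seed <- oversample_seed + match(id, names(crop$z_starts))
        imgs <- lapply(imgs, oversample_to_depth, target_z = crop$z_size,
                       seed = seed)
        label <- oversample_to_depth(label, crop$z_size, seed)
        zs <- seq_len(crop$z_size)
      } else {
        zs <- seq(crop$z_starts[[id]], length.out = crop$z_size)
      }
      n_lesion_before <- sum(label$voxels)
      xs <- if (variant == "BRS_OV")
        seq(crop$x_start, length.out = crop$x_size) else NULL
      if (!is.null(xs) && max(xs) > dim(label$voxels)[2])
        stop("crop exceeds volume height for patient ", id,
             ": reduce the safe distance")
      imgs <- lapply(imgs, crop_volume, xs = xs, zs = zs)
      label <- crop_volume(label, xs = xs, zs = zs)
      if (sum(label$voxels) != n_lesion_before)
        stop("lesion voxels of patient ", id, " fall outside the ", variant,
             " crop; the crop must contain all lesions")
    }
    patients[[id]] <- list(patient_id = id, images = imgs, label = label)
  }
  shape_record <- lapply(patients, function(p) dim(p$label$voxels))
  structure(list(variant = variant, patients = patients,
                 shape_record = shape_record, crop = crop,
                 excluded = excluded),
            class = "dataset_variant")
}

#' @export
print.dataset_variant <- function(x, ...) {
  shp <- if (length(x$shape_record))
    paste(x$shape_record[[1]], collapse = "x") else "-"
  cat(sprintf("<dataset_variant> %s: %d patients, shape %s\n",
              x$variant, length(x$patients), shp))
  invisible(x)
}

#' Shape bookkeeping between two variants
#'
#' Percentage reduction in slice count and in per-slice (in-plane) size
#' between a full-volume shape and an optimized shape.
#'
#' @param shape_full,shape_opt Integer length-3 `(X, Y, Z)` shapes.
#' @return List with `slice_reduction_pct` and `inplane_reduction_pct`.
#' @export
shape_reduction <- function(shape_full, shape_opt) {
  list(
    slice_reduction_pct = 100 * (1 - shape_opt[3] / shape_full[3]),
    inplane_reduction_pct =
      100 * (1 - (shape_opt[1] * shape_opt[2]) /
               (shape_full[1] * shape_full[2]))
  )
}
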