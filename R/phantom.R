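# Synthetic DCE-MRI phantom: paired anterior breast lobes containing
# ellipsoidal enhancing lesions, a posterior heart-like confounder that also
# enhances on the first post-contrast series, low-intensity background noise
# and optional high-intensity artifacts in the early/late slices.

#' Phantom cohort configuration
#'
#' Defaults describe the full-size study conditions: `352 x 352 x 150` voxels
#' at 1 mm in-plane spacing, 48 patients, at least 70% lesion-free slices per
#' volume, and lesions biased toward the left breast.
#'
#' @param n_patients Number of patients to simulate.
#' @param volume_shape Integer length-3 `(X, Y, Z)` voxel counts.
#' @param voxel_spacing mm per axis.
#' @param lesion_count_range `(min, max)` lesions per patient, min >= 1.
#' @param lesion_radius_range `(min, max)` lesion radius in mm, min > 0.
#' @param min_lesion_free_slice_fraction Lower bound in `[0, 1)` on the
#'   fraction of slices with no lesion voxels, enforced by construction.
#' @param enhancement_factor Multiplicative uplift applied to lesion and heart
#'   intensities on the first post-contrast series (> 1).
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @param artifact_slices Number of early and late slices receiving
#'   high-intensity artifacts outside the breast region (0 disables).
#' @param left_breast_bias Probability that a lesion is placed in the left
#'   breast (the small-`y` half-space).
#' @param seed Integer seed; the full cohort is deterministic given the
#'   configuration.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_patients = 48L,
                           volume_shape = c(352L, 352L, 150L),
                           voxel_spacing = c(1, 1, 1),
                           lesion_count_range = c(1L, 3L),
                           lesion_radius_range = c(3, 8),
                           min_lesion_free_slice_fraction = 0.70,
                           enhancement_factor = 1.8,
                           noise_sd = 5,
                           artifact_slices = 4L,
                           left_breast_bias = 0.7,
                           seed = 42L) {
  cfg <- list(n_patients = as.integer(n_patients),
              volume_shape = as.integer(volume_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              lesion_count_range = as.integer(lesion_count_range),
              lesion_radius_range = as.numeric(lesion_radius_range),
              min_lesion_free_slice_fraction =
                as.numeric(min_lesion_free_slice_fraction),
              enhancement_factor = as.numeric(enhancement_factor),
              noise_sd = as.numeric(noise_sd),
              artifact_slices = as.integer(artifact_slices),
              left_breast_bias = as.numeric(left_breast_bias),
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$n_patients < 0L)
    stop("configuration error: `n_patients` must be >= 0")
  if (length(cfg$volume_shape) != 3L || any(cfg$volume_shape < 8L))
    stop("configuration error: `volume_shape` must be three voxel counts >= 8")
  if (length(cfg$voxel_spacing) != 3L || any(cfg$voxel_spacing <= 0))
    stop("configuration error: `voxel_spacing` must be strictly positive")
  if (cfg$lesion_count_range[1] < 1L ||
      cfg$lesion_count_range[2] < cfg$lesion_count_range[1])
    stop("configuration error: `lesion_count_range` min must be >= 1")
  if (cfg$lesion_radius_range[1] <= 0 ||
      cfg$lesion_radius_range[2] < cfg$lesion_radius_range[1])
    stop("configuration error: `lesion_radius_range` min must be > 0")
  f <- cfg$min_lesion_free_slice_fraction
  if (f < 0 || f >= 1)
    stop("configuration error: `min_lesion_free_slice_fraction` must lie in [0, 1)")
  if (cfg$enhancement_factor <= 1)
    stop("configuration error: `enhancement_factor` must be > 1")
  if (cfg$artifact_slices < 0L)
    stop("configuration error: `artifact_slices` must be >= 0")
  if (cfg$artifact_slices > cfg$volume_shape[3] %/% 2L)
    stop("configuration error: `artifact_slices` must be <= Z/2")
  if (cfg$left_breast_bias < 0 || cfg$left_breast_bias > 1)
    stop("configuration error: `left_breast_bias` must lie in [0, 1]")
  geo <- phantom_geometry(cfg$volume_shape)
  # in-plane check only: the z extent is clamped to the lesion band anyway
  max_r_vox <- max(cfg$lesion_radius_range) / min(cfg$voxel_spacing[1:2])
  if (max_r_vox >= 0.5 * min(geo$a_ap, geo$a_lr_lobe))
    stop("configuration error: `lesion_radius_range` maximum exceeds the ",
         "breast extent for this `volume_shape`")
  invisible(cfg)
}

# Fixed anatomical proportions of the phantom (voxel units). Arrays are
# (LR, AP, Z): dim 1 left->right, dim 2 anterior->posterior, dim 3 slices.
phantom_geometry <- function(shape) {
  LR <- shape[1]; AP <- shape[2]; Z <- shape[3]
  list(
    chest_ap  = round(0.46 * AP),         # flat chest line; breasts anterior
    a_ap      = round(0.42 * AP),         # anterior reach of all lobes
    a_lr_lobe = round(0.24 * LR),
    a_lr_mid  = round(0.14 * LR),         # medial lobe bridging the midline
    a_z       = round(0.48 * Z),
    c_left    = round(0.27 * LR),         # patient left = small dim-1 index
    c_right   = round(0.73 * LR),
    c_mid     = round(0.50 * LR),
    cz        = round(0.50 * Z),
    heart_c   = c(round(0.50 * LR), round(0.46 * AP) + round(0.22 * AP),
                  round(0.50 * Z)),
    heart_a   = c(round(0.15 * LR), round(0.13 * AP), round(0.30 * Z))
  )
}

# Quadratic form grid ((i-c)/a)^2 summed over axes, as a full 3D array.
ellipsoid_field <- function(shape, centre, semi) {
  qx <- ((seq_len(shape[1]) - centre[1]) / semi[1])^2
  qy <- ((seq_len(shape[2]) - centre[2]) / semi[2])^2
  qz <- ((seq_len(shape[3]) - centre[3]) / semi[3])^2
  outer(outer(qx, qy, "+"), qz, "+")
}

# Breast region: union of left, right and medial half-ellipsoids anterior to
# the chest line. The medial lobe makes the midline depth equal the maximal
# anterior extent, so the cohort crop-height rule covers every lesion.
phantom_region_mask <- function(shape) {
  g <- phantom_geometry(shape)
  anterior <- rep(seq_len(shape[2]) <= g$chest_ap, each = shape[1])
  inside <- (ellipsoid_field(shape, c(g$c_left, g$chest_ap, g$cz),
                             c(g$a_lr_lobe, g$a_ap, g$a_z)) <= 1) |
    (ellipsoid_field(shape, c(g$c_right, g$chest_ap, g$cz),
                     c(g$a_lr_lobe, g$a_ap, g$a_z)) <= 1) |
    (ellipsoid_field(shape, c(g$c_mid, g$chest_ap, g$cz),
                     c(g$a_lr_mid, g$a_ap, g$a_z)) <= 1)
  inside <- inside & array(anterior, dim = shape)
  array(as.integer(inside), dim = shape)
}

phantom_heart_mask <- function(shape) {
  g <- phantom_geometry(shape)
  array(as.integer(ellipsoid_field(shape, g$heart_c, g$heart_a) <= 1),
        dim = shape)
}

# Sample lesion spheres for one patient. All lesion z-extents are confined to
# one contiguous band of at most (1 - min_free) * Z slices, which enforces the
# lesion-free slice fraction by construction.
phantom_lesion_mask <- function(cfg, region) {
  shape <- cfg$volume_shape
  g <- phantom_geometry(shape)
  Z <- shape[3]
  band_len <- max(1L, floor((1 - cfg$min_lesion_free_slice_fraction) * Z))
  band_start <- sample.int(Z - band_len + 1L, 1L)
  band_end <- band_start + band_len - 1L
  n_lesions <- sample(seq(cfg$lesion_count_range[1], cfg$lesion_count_range[2]),
                      1L)
  lesion <- array(0L, dim = shape)
  sp <- cfg$voxel_spacing
  for (i in seq_len(n_lesions)) {
    # resample until the sphere overlaps breast tissue (clipping to the
    # region can otherwise empty a lesion near the volume edges)
    for (try in 1:25) {
      left <- stats::runif(1) < cfg$left_breast_bias
      c_lobe <- if (left) g$c_left else g$c_right
      r_mm <- stats::runif(1, cfg$lesion_radius_range[1],
                           cfg$lesion_radius_range[2])
      r_vox <- r_mm / sp
      # shrink the z radius so the sphere's slice extent fits the band
      r_vox[3] <- min(r_vox[3], band_len / 2)
      c_lr <- c_lobe + stats::runif(1, -0.45, 0.45) * g$a_lr_lobe
      c_ap <- g$chest_ap - stats::runif(1, 0.3, 0.75) * g$a_ap
      zlo <- band_start - 0.5 + r_vox[3]
      zhi <- band_end + 0.5 - r_vox[3]
      cz <- if (zlo >= zhi) (band_start + band_end) / 2 else
        stats::runif(1, zlo, zhi)
      sphere <- (ellipsoid_field(shape, c(c_lr, c_ap, cz),
                                 pmax(r_vox, 0.5)) <= 1) & (region > 0)
      if (any(sphere)) break
    }
    lesion <- lesion | sphere
  }
  # containment: lesions are breast tissue by definition
  array(as.integer(lesion & (region > 0)), dim = shape)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  expr
}

#' Generate a synthetic cohort
#'
#' Deterministically builds `n_patients` phantom records: pre-contrast (PC)
#' and first post-contrast (FPC) volumes, subtraction image, ground-truth
#' breast-region and lesion masks. Lesion voxels are always contained in the
#' breast region, the FPC series exceeds PC inside lesions and the heart blob,
#' and the fraction of lesion-free slices meets the configured minimum.
#'
#' @param config A [phantom_config()].
#' @param out_dir Optional directory; when given, every series is written as
#'   NIfTI with an RAS affine and a JSON cohort manifest is created.
#' @return A list of `patient_record` objects (empty list for
#'   `n_patients = 0`).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  validate_phantom_config(config)
  records <- with_preserved_rng({
    set.seed(config$seed)
    lapply(seq_len(config$n_patients), function(i) {
      generate_patient(config, sprintf("phantom%03d", i))
    })
  })
  if (!is.null(out_dir)) write_cohort(records, out_dir)
  records
}

generate_patient <- function(cfg, patient_id) {
  shape <- cfg$volume_shape
  region <- phantom_region_mask(shape)
  heart <- phantom_heart_mask(shape)
  lesion <- phantom_lesion_mask(cfg, region)

  base <- array(20, dim = shape)
  base[region > 0] <- 100
  base[heart > 0] <- 140
  base[lesion > 0] <- 150
  pc_arr <- base + array(stats::rnorm(prod(shape), 0, cfg$noise_sd),
                         dim = shape)
  enhanced <- base
  uplift <- (lesion > 0) | (heart > 0)
  enhanced[uplift] <- enhanced[uplift] * cfg$enhancement_factor
  fpc_arr <- enhanced + array(stats::rnorm(prod(shape), 0, cfg$noise_sd),
                              dim = shape)

  sp <- cfg$voxel_spacing
  rec <- patient_record(
    patient_id = patient_id,
    pc = image_volume(pc_arr, sp, role = "PC", patient_id = patient_id),
    fpc = image_volume(fpc_arr, sp, role = "FPC", patient_id = patient_id),
    region_mask = mask_volume(region, sp, kind = "REGION",
                              patient_id = patient_id),
    lesion_mask = mask_volume(lesion, sp, kind = "LESION",
                              patient_id = patient_id),
    complete = TRUE
  )
  rec$subtraction <- subtract(rec$fpc, rec$pc)
  if (cfg$artifact_slices > 0L) rec <- inject_artifacts(rec, cfg) else rec
}

#' Patient record
#'
#' Bundles all per-patient series and masks; every member shares shape,
#' spacing and orientation, and every lesion voxel is breast-region
#' foreground.
#'
#' @param patient_id Character id.
#' @param pc,fpc [image_volume()] pre-contrast / first post-contrast series.
#' @param region_mask,lesion_mask [mask_volume()] ground truth masks.
#' @param subtraction Optional [image_volume()].
#' @param complete Logical completeness flag (exclusion semantics).
#' @param incomplete_reason Character reason when `complete = FALSE`.
#' @return A `patient_record`.
#' @export
patient_record <- function(patient_id, pc = NULL, fpc = NULL,
                           region_mask = NULL, lesion_mask = NULL,
                           subtraction = NULL, complete = TRUE,
                           incomplete_reason = NULL) {
  rec <- structure(
    list(patient_id = patient_id, pc = pc, fpc = fpc,
         subtraction = subtraction, region_mask = region_mask,
         lesion_mask = lesion_mask, complete = complete,
         incomplete_reason = incomplete_reason),
    class = "patient_record")
  if (complete) validate_patient_record(rec)
  rec
}

validate_patient_record <- function(rec) {
  vols <- Filter(Negate(is.null),
                 rec[c("pc", "fpc", "subtraction", "region_mask",
                       "lesion_mask")])
  if (length(vols) > 1) {
    ref <- vols[[1]]
    for (v in vols[-1]) stop_if_geometry_mismatch(ref, v, "patient series")
  }
  if (!is.null(rec$lesion_mask) && !is.null(rec$region_mask)) {
    outside <- sum(rec$lesion_mask$voxels > rec$region_mask$voxels)
    if (outside > 0)
      stop("invalid patient record: ", outside,
           " lesion voxels fall outside the breast region")
  }
  invisible(rec)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s complete=%s\n", x$patient_id, x$complete))
  invisible(x)
}

#' Inject early/late slice artifacts
#'
#' Adds high-intensity structures to the first and last `artifact_slices`
#' slices of the PC and FPC series, restricted to voxels outside the breast
#' region mask. The lesion mask is untouched.
#'
#' @param record A [patient_record()].
#' @param config A [phantom_config()]; `artifact_slices` and `seed` are used.
#' @return The modified record.
#' @export
inject_artifacts <- function(record, config) {
  k <- config$artifact_slices
  if (k < 0L) stop("configuration error: `artifact_slices` must be >= 0")
  Z <- dim(record$pc$voxels)[3]
  if (k > Z %/% 2L)
    stop("configuration error: `artifact_slices` must be <= Z/2")
  if (k == 0L) return(record)
  shape <- dim(record$pc$voxels)
  slices <- c(seq_len(k), seq(Z - k + 1L, Z))
  with_preserved_rng({
    set.seed(config$seed + 10007L * sum(utf8ToInt(record$patient_id)))
    bg <- record$region_mask$voxels == 0L
    for (z in slices) {
      for (b in 1:3) {
        w <- sample(seq(max(3L, shape[1] %/% 20L), max(4L, shape[1] %/% 8L)), 1)
        h <- sample(seq(max(3L, shape[2] %/% 20L), max(4L, shape[2] %/% 8L)), 1)
        # anchored in the far posterior strip, which is always background
        lr0 <- sample(seq_len(shape[1] - w), 1)
        ap0 <- sample(seq(round(0.8 * shape[2]), shape[2] - h), 1)
        lrs <- lr0:(lr0 + w - 1L); aps <- ap0:(ap0 + h - 1L)
        sel <- bg[lrs, aps, z]
        pc_sl <- record$pc$voxels[lrs, aps, z]
        fpc_sl <- record$fpc$voxels[lrs, aps, z]
        pc_sl[sel] <- pc_sl[sel] + 180
        fpc_sl[sel] <- fpc_sl[sel] + 180
        record$pc$voxels[lrs, aps, z] <- pc_sl
        record$fpc$voxels[lrs, aps, z] <- fpc_sl
      }
    }
  })
  if (!is.null(record$subtraction))
    record$subtraction <- subtract(record$fpc, record$pc)
  record
}

#' Write a cohort to disk
#'
#' One NIfTI file per series plus a JSON manifest listing patient ids, file
#' paths and completeness flags.
#'
#' @param records List of [patient_record()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(records, function(rec) {
    pdir <- file.path(dir, rec$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    paths <- list()
    for (series in c("pc", "fpc", "subtraction", "region_mask",
                     "lesion_mask")) {
      if (is.null(rec[[series]])) next
      p <- file.path(pdir, paste0(series, ".nii.gz"))
      write_volume(rec[[series]], p)
      paths[[series]] <- p
    }
    list(patient_id = rec$patient_id, complete = rec$complete,
         files = paths)
  })
  mpath <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
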