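# Threshold-based segmentation metrics, lesion-volume-stratified FP/FN
# counting on 3D connected components, and carbon-footprint accounting.

#' Binarize a probability map
#'
#' Voxels with probability `>= threshold` become foreground (ties count as
#' foreground; the stratified FP/FN tables depend on this convention).
#'
#' @param p Array of probabilities in `[0, 1]`.
#' @param threshold Probability threshold in `(0, 1)`, default 0.5.
#' @param spacing,patient_id Metadata for the resulting mask.
#' @return A [mask_volume()] of kind `"PREDICTION"`.
#' @export
binarize <- function(p, threshold = 0.5, spacing = c(1, 1, 1),
                     patient_id = "unknown") {
  if (threshold <= 0 || threshold >= 1)
    stop("configuration error: `threshold` must lie strictly in (0, 1)")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (length(dim(p)) == 2L) dim(p) <- c(dim(p), 1L)
  mask_volume(array(as.integer(p >= threshold), dim = dim(p)),
              spacing = spacing, kind = "PREDICTION",
              patient_id = patient_id)
}

#' Voxel confusion counts
#'
#' @param pred,gt Binary [mask_volume()]s with matching geometry.
#' @return List with `tp`, `fp`, `fn`, `tn` (their sum is the voxel count).
#' @export
confusion_counts <- function(pred, gt) {
  stop_if_geometry_mismatch(pred, gt, "prediction and ground truth")
  p <- pred$voxels; g <- gt$voxels
  tp <- sum(p == 1 & g == 1)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  list(tp = tp, fp = fp, fn = fn, tn = length(p) - tp - fp - fn)
}

#' Segmentation metrics
#'
#' Dice `2TP/(2TP+FP+FN)`, IoU `TP/(TP+FP+FN)`, precision `TP/(TP+FP)` and
#' recall `TP/(TP+FN)`. When prediction and ground truth are both empty all
#' metrics are 1; when exactly one is empty they are 0.
#'
#' @param pred,gt Binary [mask_volume()]s with matching geometry.
#' @return A `seg_metrics` list with `dice`, `iou`, `precision`, `recall`.
#' @export
seg_metrics <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  both_empty <- cc$tp + cc$fp + cc$fn == 0
  metrics <- if (both_empty) {
    list(dice = 1, iou = 1, precision = 1, recall = 1)
  } else {
    safe <- function(num, den) if (den == 0) 0 else num / den
    list(dice = safe(2 * cc$tp, 2 * cc$tp + cc$fp + cc$fn),
         iou = safe(cc$tp, cc$tp + cc$fp + cc$fn),
         precision = safe(cc$tp, cc$tp + cc$fp),
         recall = safe(cc$tp, cc$tp + cc$fn))
  }
  structure(c(metrics, list(counts = cc)), class = "seg_metrics")
}

#' Label 3D connected components (26-connectivity)
#'
#' @param voxels Binary 3D array.
#' @return Integer array of labels, `0` = background, with attribute
#'   `n_components`.
#' @export
label_components <- function(voxels) {
  if (!all(voxels %in% c(0, 1))) stop("contract error: input must be binary")
  d <- dim(voxels)
  lab <- .cc_label_26(as.integer(voxels), d)
  n <- attr(lab, "n_components")
  lab <- array(lab, dim = d)
  attr(lab, "n_components") <- n
  lab
}

lesion_volume_bins <- c(10, 20)  # mm^3 boundaries: V<10, 10<=V<=20, V>20

bin_volume <- function(v) {
  if (v < lesion_volume_bins[1]) 1L
  else if (v <= lesion_volume_bins[2]) 2L
  else 3L
}

#' Volume-stratified FP/FN lesion counts
#'
#' Connected components are computed in 3D with 26-connectivity. A predicted
#' component with zero voxel overlap with the ground truth is a false
#' positive; a ground-truth component with zero overlap with the prediction
#' is a false negative. Component volume is voxel count times voxel volume
#' (mm^3), binned as `V < 10`, `10 < V < 20`, `V > 20` (boundary values go
#' to the middle bin).
#'
#' @param pred,gt Binary [mask_volume()]s.
#' @param spacing Voxel spacing in mm (defaults to the prediction's).
#' @param threshold Threshold recorded in the report (provenance only).
#' @return A `lesion_match_report`: `fp_by_bin`, `fn_by_bin`,
#'   `n_pred_components`, `n_gt_components`, `n_matched_pred`, `threshold`.
#' @export
lesion_match <- function(pred, gt, spacing = NULL, threshold = 0.5) {
  stop_if_geometry_mismatch(pred, gt, "prediction and ground truth")
  if (is.null(spacing)) spacing <- pred$spacing
  voxvol <- prod(spacing)
  pl <- label_components(pred$voxels)
  gl <- label_components(gt$voxels)
  np <- attr(pl, "n_components"); ng <- attr(gl, "n_components")

  bins <- c("V<10", "10<V<20", "V>20")
  fp_by_bin <- stats::setNames(integer(3), bins)
  fn_by_bin <- stats::setNames(integer(3), bins)
  n_matched <- 0L
  if (np > 0) {
    overlap <- tabulate(pl[pl > 0 & gt$voxels > 0], nbins = np)
    sizes <- tabulate(pl[pl > 0], nbins = np)
    for (k in seq_len(np)) {
      if (overlap[k] > 0) n_matched <- n_matched + 1L
      else {
        b <- bin_volume(sizes[k] * voxvol)
        fp_by_bin[b] <- fp_by_bin[b] + 1L
      }
    }
  }
  if (ng > 0) {
    overlap <- tabulate(gl[gl > 0 & pred$voxels > 0], nbins = ng)
    sizes <- tabulate(gl[gl > 0], nbins = ng)
    for (k in seq_len(ng)) {
      if (overlap[k] == 0) {
        b <- bin_volume(sizes[k] * voxvol)
        fn_by_bin[b] <- fn_by_bin[b] + 1L
      }
    }
  }
  structure(list(fp_by_bin = fp_by_bin, fn_by_bin = fn_by_bin,
                 n_pred_components = np, n_gt_components = ng,
                 n_matched_pred = n_matched, threshold = threshold),
            class = "lesion_match_report")
}

#' Carbon footprint of a training fold
#'
#' `CFP = 0.475 * TT / 3600` kg CO2, with `TT` the per-fold training time in
#' seconds: a 1 kW training session at an average grid intensity of 475 g
#' CO2 per kWh.
#'
#' @param tt_seconds Training time in seconds (>= 0).
#' @return kg CO2.
#' @export
carbon_footprint <- function(tt_seconds) {
  if (any(tt_seconds < 0)) stop("contract error: training time must be >= 0")
  0.475 * tt_seconds / 3600
}

#' Normalized carbon footprint
#'
#' `Norm_CFP = 1 - (CFP_max - CFP_min) * (CFP / CFP_max)`, computed
#' literally. Note the expression is dimensionally odd (a kg-valued
#' difference scales a dimensionless ratio) and is not guaranteed to lie in
#' `[0, 1]`; it is reported as defined.
#'
#' @param cfp Footprint of the approach under evaluation (kg CO2).
#' @param cfp_max,cfp_min Extreme per-fold footprints across approaches.
#' @return Normalized score (higher = more efficient).
#' @export
normalized_cfp <- function(cfp, cfp_max, cfp_min) {
  if (cfp_max <= 0) stop("contract error: `cfp_max` must be > 0")
  if (cfp_min < 0 || cfp_max < cfp_min)
    stop("contract error: need cfp_max >= cfp_min >= 0")
  1 - (cfp_max - cfp_min) * (cfp / cfp_max)
}

#' Headline comparison statistics
#'
#' Percent Dice increase of the optimal-volume approach over the
#' no-BRS whole-volume baseline, `100 * (dice_OV - dice_base) / dice_base`,
#' and the energy ratio `100 * cfp_base / cfp_OV`.
#'
#' @param metric_table Data frame with columns `method` and `dice`.
#' @param energy_table Data frame with columns `method` and `cfp`.
#' @param baseline,optimal Method labels of the baseline and OV rows.
#' @return List with `dice_increase_pct` and `energy_ratio_pct`; either is
#'   `NA` (with `available = FALSE`) when a row is missing.
#' @export
improvement_stats <- function(metric_table, energy_table,
                              baseline = "WV", optimal = "BRS_OV") {
  pick <- function(tab, col, method) {
    i <- match(method, tab$method)
    if (is.na(i)) NA_real_ else tab[[col]][i]
  }
  d0 <- pick(metric_table, "dice", baseline)
  d1 <- pick(metric_table, "dice", optimal)
  c0 <- pick(energy_table, "cfp", baseline)
  c1 <- pick(energy_table, "cfp", optimal)
  dice_inc <- if (anyNA(c(d0, d1)) || d0 == 0) NA_real_ else
    100 * (d1 - d0) / d0
  eratio <- if (anyNA(c(c0, c1)) || c1 == 0) NA_real_ else 100 * c0 / c1
  list(dice_increase_pct = dice_inc, energy_ratio_pct = eratio,
       available = !anyNA(c(dice_inc, eratio)))
}

#' Evaluate a cross-validation result on its test holdout
#'
#' Each fold's best checkpoint predicts the held-out test patients; the
#' probability volumes are thresholded and scored. Reported metrics are the
#' mean over test patients (and folds); FP/FN bins are summed.
#'
#' @param cv A `cv_result` from [train_cv()].
#' @param variant The `dataset_variant` the result was trained on.
#' @param threshold Binarization threshold.
#' @return An `eval_report` with per-patient metrics, aggregate means,
#'   summed FP/FN bins and the per-fold energy table.
#' @export
evaluate_cv <- function(cv, variant, threshold = 0.5) {
  cs <- cv$train_cfg$channel_selection
  rows <- list()
  fp <- fn <- stats::setNames(integer(3), c("V<10", "10<V<20", "V>20"))
  for (fr in cv$folds) {
    model <- build_model(cv$model_cfg, quiet = TRUE)
    set_model_state(model, fr$best_state)
    for (id in cv$test_patients) {
      pat <- variant$patients[[id]]
      prob <- predict_patient(model, pat, cs, cv$train_cfg$normalize,
                              cv$train_cfg$batch_size)
      pred <- binarize(prob, threshold, spacing = pat$label$spacing,
                       patient_id = id)
      m <- seg_metrics(pred, pat$label)
      lm <- lesion_match(pred, pat$label, threshold = threshold)
      fp <- fp + lm$fp_by_bin
      fn <- fn + lm$fn_by_bin
      rows[[paste(fr$fold, id)]] <-
        data.frame(fold = fr$fold, patient = id, dice = m$dice, iou = m$iou,
                   precision = m$precision, recall = m$recall)
    }
  }
  per_patient <- do.call(rbind, rows)
  energy <- data.frame(
    fold = vapply(cv$folds, `[[`, numeric(1), "fold"),
    tt_seconds = vapply(cv$folds, `[[`, numeric(1), "tt_seconds"),
    last_epoch = vapply(cv$folds, function(f) max(f$history$epoch),
                        numeric(1)))
  energy$cfp <- carbon_footprint(energy$tt_seconds)
  structure(list(
    variant = cv$variant, threshold = threshold,
    per_patient = per_patient,
    mean_metrics = colMeans(per_patient[, c("dice", "iou", "precision",
                                            "recall")]),
    fp_by_bin = fp, fn_by_bin = fn, energy = energy),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s @ %.2f: dice %.3f iou %.3f prec %.3f rec %.3f\n",
              x$variant, x$threshold, x$mean_metrics["dice"],
              x$mean_metrics["iou"], x$mean_metrics["precision"],
              x$mean_metrics["recall"]))
  invisible(x)
}

#' Write an evaluation report to JSON and CSV
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jp <- file.path(dir, paste0("report_", report$variant, ".json"))
  jsonlite::write_json(
    list(variant = report$variant, threshold = report$threshold,
         mean_metrics = as.list(report$mean_metrics),
         fp_by_bin = as.list(report$fp_by_bin),
         fn_by_bin = as.list(report$fn_by_bin),
         energy = report$energy),
    jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cp <- file.path(dir, paste0("metrics_", report$variant, ".csv"))
  utils::write.csv(report$per_patient, cp, row.names = FALSE)
  invisible(c(jp, cp))
}
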