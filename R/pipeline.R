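# End-to-end orchestration: simulate -> mask -> crop -> overlay -> train ->
# evaluate -> report, with per-stage seeds and provenance manifests.

stage_seed <- function(global_seed, stage) {
  # stable per-stage seed: hash of the stage name folded into the global seed
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h * 104729) %% 2147483563)
}

#' Pipeline configuration
#'
#' Bundles all stage configurations. Per-stage seeds are derived from
#' `global_seed` by stable hashing of the stage name, so stages are
#' decoupled and each is reproducible in isolation.
#'
#' @param phantom A [phantom_config()] (its `seed` is overridden by the
#'   derived simulate seed).
#' @param safe_distance,divisor Optimal-volume crop-height parameters
#'   (defaults 16 and 32).
#' @param model A [model_config()].
#' @param train A [train_config()].
#' @param loss A [hybrid_loss_config()].
#' @param variants Subset of `c("WV", "BRS_WV", "BRS_SLS", "BRS_OV")`.
#' @param mask_source `"groundtruth"` or `"heuristic"` breast-region masks.
#' @param output_root Run directory root.
#' @param global_seed Master seed.
#' @param write_volumes Also write the simulated cohort as NIfTI.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            safe_distance = 16L, divisor = 32L,
                            model = model_config(),
                            train = train_config(),
                            loss = hybrid_loss_config(),
                            variants = VARIANTS,
                            mask_source = "groundtruth",
                            output_root = tempfile("ovseg_run_"),
                            global_seed = 42L,
                            write_volumes = FALSE) {
  variants <- match.arg(variants, VARIANTS, several.ok = TRUE)
  structure(list(phantom = phantom, safe_distance = as.integer(safe_distance),
                 divisor = as.integer(divisor), model = model, train = train,
                 loss = loss, variants = variants, mask_source = mask_source,
                 output_root = output_root,
                 global_seed = as.integer(global_seed),
                 write_volumes = write_volumes),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; nested keys are
#' passed to the respective stage constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_config, y$phantom)
  if (!is.null(y$model)) args$model <- do.call(model_config, y$model)
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$loss)) args$loss <- do.call(hybrid_loss_config, y$loss)
  for (k in c("safe_distance", "divisor", "variants", "mask_source",
              "output_root", "global_seed", "write_volumes"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' Simulates a cohort, derives region masks, builds the requested dataset
#' variants, computes overlay analytics, trains the nested-UNet per variant
#' under cross-validation, evaluates on the test holdout and writes the
#' comparison report. Deterministic artifacts (manifests, shape records,
#' histories, metrics) are identical across re-runs with the same
#' configuration; wall-clock fields live in a separate timing file.
#'
#' @param cfg A [pipeline_config()].
#' @return The run directory, invisibly; a `run_manifest.json` inside it
#'   records every stage's seeds, inputs and outputs.
#' @export
run_pipeline <- function(cfg) {
  run_dir <- cfg$output_root
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(global_seed = cfg$global_seed, stages = list())
  timings <- list()
  fail <- function(stage, e, patient = NA)
    stop("pipeline stage '", stage, "' failed",
         if (!is.na(patient)) paste0(" (patient ", patient, ")"), ": ",
         conditionMessage(e), call. = FALSE)

  # simulate
  t0 <- proc.time()[["elapsed"]]
  sim_seed <- stage_seed(cfg$global_seed, "simulate")
  phantom <- cfg$phantom; phantom$seed <- sim_seed
  records <- tryCatch(generate_cohort(phantom),
                      error = function(e) fail("simulate", e))
  if (cfg$write_volumes) write_cohort(records, file.path(run_dir, "cohort"))
  manifest$stages$simulate <- list(seed = sim_seed,
                                   n_patients = length(records),
                                   shape = phantom$volume_shape)
  timings$simulate <- proc.time()[["elapsed"]] - t0

  # mask + crop
  t0 <- proc.time()[["elapsed"]]
  crop <- tryCatch(
    compute_crop_spec(records, cfg$safe_distance, cfg$divisor,
                      cfg$mask_source),
    error = function(e) fail("crop", e))
  variants <- list()
  for (v in cfg$variants) {
    variants[[v]] <- tryCatch(
      build_variant(records, v, crop = crop, mask_source = cfg$mask_source,
                    oversample_seed = stage_seed(cfg$global_seed, "crop")),
      error = function(e) fail("crop", e))
  }
  manifest$stages$crop <- list(
    seed = stage_seed(cfg$global_seed, "crop"),
    safe_distance = cfg$safe_distance, divisor = cfg$divisor,
    x_start = crop$x_start, x_size = crop$x_size, z_size = crop$z_size,
    excluded = attr(crop, "excluded"),
    shapes = lapply(variants, function(dv)
      lapply(dv$shape_record, as.integer)))
  jsonlite::write_json(manifest$stages$crop,
                       file.path(run_dir, "variant_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  timings$crop <- proc.time()[["elapsed"]] - t0

  # overlay analytics
  t0 <- proc.time()[["elapsed"]]
  overlay_summary <- list()
  for (v in names(variants)) {
    dv <- variants[[v]]
    lesions <- lapply(dv$patients, `[[`, "label")
    om <- overlay_map(unname(lesions))
    write_overlay(om, file.path(run_dir, "overlay", paste0(v, "_lesion")))
    overlay_summary[[v]] <- list(lesion_total = sum(om$grid),
                                 h_max_mid = midline_span(om)$h_max_mid)
  }
  manifest$stages$overlay <- overlay_summary
  timings$overlay <- proc.time()[["elapsed"]] - t0

  # train + evaluate
  metric_rows <- list(); energy_rows <- list()
  train_seed <- stage_seed(cfg$global_seed, "train")
  for (v in names(variants)) {
    t0 <- proc.time()[["elapsed"]]
    tcfg <- cfg$train; tcfg$seed <- train_seed
    cv <- tryCatch(train_cv(variants[[v]], cfg$model, tcfg, cfg$loss),
                   error = function(e) fail("train", e))
    vdir <- file.path(run_dir, "train", v)
    dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
    for (fr in cv$folds) {
      utils::write.csv(fr$history,
                       file.path(vdir, sprintf("fold%d_history.csv", fr$fold)),
                       row.names = FALSE)
      saveRDS(fr$best_state,
              file.path(vdir, sprintf("fold%d_checkpoint.rds", fr$fold)))
      jsonlite::write_json(
        list(variant = v, fold = fr$fold, best_epoch = fr$best_epoch,
             best_val_loss = fr$best_val_loss, seed = train_seed),
        file.path(vdir, sprintf("fold%d_checkpoint.json", fr$fold)),
        auto_unbox = TRUE, digits = NA)
    }
    rep <- tryCatch(evaluate_cv(cv, variants[[v]]),
                    error = function(e) fail("evaluate", e))
    write_report(rep, file.path(run_dir, "eval"))
    metric_rows[[v]] <- data.frame(method = v,
                                   dice = rep$mean_metrics[["dice"]],
                                   iou = rep$mean_metrics[["iou"]])
    energy_rows[[v]] <- data.frame(method = v,
                                   tt_seconds = mean(rep$energy$tt_seconds),
                                   cfp = mean(rep$energy$cfp))
    timings[[paste0("train_", v)]] <- proc.time()[["elapsed"]] - t0
  }

  # report
  metric_table <- do.call(rbind, metric_rows)
  energy_table <- do.call(rbind, energy_rows)
  energy_table$norm_cfp <- if (nrow(energy_table) > 0 &&
                               max(energy_table$cfp) > 0)
    normalized_cfp(energy_table$cfp, max(energy_table$cfp),
                   min(energy_table$cfp)) else NA_real_
  comp <- improvement_stats(metric_table, energy_table)
  jsonlite::write_json(
    list(metrics = metric_table, energy = energy_table, comparison = comp),
    file.path(run_dir, "comparison_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")

  manifest$stages$train <- list(seed = train_seed,
                                variants = names(variants))
  jsonlite::write_json(manifest, file.path(run_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(timings, file.path(run_dir, "timings.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(run_dir)
}
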