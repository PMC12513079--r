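# Patient-level 5-fold cross-validated training of the nested-UNet on a
# dataset variant, slice by slice, with the hybrid loss, RAdam and a
# reduce-on-plateau learning-rate schedule.

#' Training configuration
#'
#' Study defaults: RAdam with initial learning rate 0.001, a
#' reduce-on-plateau scheduler, batch size 8, 5 folds, a 2-patient test
#' holdout, and training-only shuffling. Folds are split at the patient
#' level to prevent slice leakage between training and validation.
#'
#' @param learning_rate Initial learning rate.
#' @param scheduler_factor Multiplier applied when the validation loss
#'   plateaus.
#' @param scheduler_patience Epochs without improvement before the rate
#'   drops.
#' @param scheduler_min_lr Floor for the learning rate.
#' @param batch_size Slices per training batch.
#' @param folds Number of cross-validation folds (>= 2).
#' @param test_holdout_patients Patients removed before folding.
#' @param max_epochs Upper bound on epochs per fold.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param seed Seed controlling holdout choice, fold assignment, weight
#'   initialization and shuffling.
#' @param channel_selection Subset of `c("PC", "FPC", "SUBTRACTION")` used
#'   as input channels.
#' @param normalize Min-max normalize each input volume.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, scheduler_factor = 0.5,
                         scheduler_patience = 3L, scheduler_min_lr = 1e-5,
                         batch_size = 8L, folds = 5L,
                         test_holdout_patients = 2L, max_epochs = 50L,
                         early_stop_patience = 8L, seed = 1L,
                         channel_selection = "SUBTRACTION",
                         normalize = TRUE) {
  if (folds < 2L) stop("configuration error: `folds` must be >= 2")
  if (batch_size < 1L) stop("configuration error: `batch_size` must be >= 1")
  stopifnot(all(channel_selection %in% c("PC", "FPC", "SUBTRACTION")))
  structure(list(optimizer = "radam", learning_rate = learning_rate,
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 scheduler_min_lr = scheduler_min_lr,
                 batch_size = as.integer(batch_size),
                 folds = as.integer(folds),
                 test_holdout_patients = as.integer(test_holdout_patients),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed),
                 channel_selection = channel_selection,
                 normalize = normalize),
            class = "train_config")
}

# fold a pair of integers into a valid 32-bit seed
mix_seed <- function(a, b) {
  as.integer((as.numeric(a) * 48271 + as.numeric(b) * 16807) %% 2147483563)
}

#' Patient-level fold assignment
#'
#' Removes a random test holdout, then partitions the remaining patients
#' into patient-disjoint folds. Deterministic given the seed.
#'
#' @param patient_ids Character vector of ids.
#' @param folds Number of folds.
#' @param holdout Test patients to set aside.
#' @param seed Integer seed.
#' @return List with `test` (ids) and `folds` (list of id vectors, the
#'   validation set of each fold).
#' @export
assign_folds <- function(patient_ids, folds, holdout, seed) {
  n <- length(patient_ids)
  if (n < folds + holdout)
    stop("configuration error: need at least ", folds + holdout,
         " patients for ", folds, "-fold cross-validation with a ",
         holdout, "-patient holdout (got ", n, ")")
  with_preserved_rng({
    set.seed(seed)
    ids <- sample(patient_ids)
  })
  test <- if (holdout > 0) ids[seq_len(holdout)] else character(0)
  rest <- ids[seq(holdout + 1, n)]
  assignment <- rep(seq_len(folds), length.out = length(rest))
  list(test = test, folds = split(rest, assignment))
}

# Pooled (H, W, C, S) stack plus (H, W, S) labels for a set of patients.
pooled_slices <- function(variant, ids, channels, normalize) {
  xs <- list(); gs <- list()
  for (id in ids) {
    p <- variant$patients[[id]]
    xs[[id]] <- patient_slice_stack(p, channels, normalize)
    gs[[id]] <- p$label$voxels
  }
  d <- dim(xs[[1]])
  n_slices <- sum(vapply(xs, function(a) dim(a)[4], numeric(1)))
  x <- array(0, dim = c(d[1], d[2], d[3], n_slices))
  g <- array(0, dim = c(d[1], d[2], n_slices))
  at <- 0L
  for (id in ids) {
    k <- dim(xs[[id]])[4]
    x[, , , at + seq_len(k)] <- xs[[id]]
    g[, , at + seq_len(k)] <- gs[[id]]
    at <- at + k
  }
  list(x = x, g = g, n = n_slices)
}

#' Cross-validated training
#'
#' Removes the test holdout, then trains one model per fold on the training
#' patients' slices (shuffled each epoch) while monitoring the hybrid loss
#' on the validation patients' slices. Learning rate follows a
#' reduce-on-plateau schedule; the best validation state per fold is kept,
#' and per-fold wall-clock training time is recorded for the energy report.
#'
#' @param variant A `dataset_variant` from [build_variant()].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param loss_cfg A [hybrid_loss_config()].
#' @param verbose Print per-epoch losses.
#' @return A `cv_result`: per-fold histories, best checkpoints, wall-clock
#'   seconds, plus the test patient ids and the configurations used.
#' @export
train_cv <- function(variant, model_cfg = model_config(),
                     train_cfg = train_config(),
                     loss_cfg = hybrid_loss_config(), verbose = FALSE) {
  ids <- names(variant$patients)
  split <- assign_folds(ids, train_cfg$folds, train_cfg$test_holdout_patients,
                        train_cfg$seed)
  non_test <- setdiff(ids, split$test)
  cs <- train_cfg$channel_selection
  if (length(cs) != model_cfg$in_channels)
    stop("configuration error: `in_channels` must match the channel selection")

  fold_results <- list()
  for (f in seq_len(train_cfg$folds)) {
    val_ids <- split$folds[[f]]
    train_ids <- setdiff(non_test, val_ids)
    tr <- pooled_slices(variant, train_ids, cs, train_cfg$normalize)
    va <- pooled_slices(variant, val_ids, cs, train_cfg$normalize)

    t0 <- proc.time()[["elapsed"]]
    model <- with_preserved_rng({
      set.seed(mix_seed(train_cfg$seed, f))
      build_model(model_cfg, quiet = TRUE)
    })
    lr <- train_cfg$learning_rate
    best_val <- Inf; best_state <- NULL; best_epoch <- 0L
    plateau <- 0L; stall <- 0L
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric(), lr = numeric())

    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- with_preserved_rng({
        set.seed(mix_seed(train_cfg$seed, f * 1000L + epoch))
        sample.int(tr$n)
      })
      batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
      losses <- vapply(batches, function(ix) {
        .unetpp_train_batch(model$ptr,
                            tr$x[, , , ix, drop = FALSE],
                            tr$g[, , ix, drop = FALSE],
                            lr, loss_cfg$alpha, loss_cfg$beta,
                            loss_cfg$gamma_w, loss_cfg$focal_alpha_t,
                            loss_cfg$focal_gamma_f)
      }, numeric(1))
      train_loss <- mean(losses)
      val_loss <- validation_loss(model, va, train_cfg$batch_size, loss_cfg)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                     val_loss = val_loss, lr = lr))
      if (verbose)
        message(sprintf("fold %d epoch %d: train %.4f val %.4f lr %.2g",
                        f, epoch, train_loss, val_loss, lr))
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss
        best_state <- model_state(model)
        best_epoch <- epoch
        plateau <- 0L; stall <- 0L
      } else {
        plateau <- plateau + 1L; stall <- stall + 1L
        if (plateau >= train_cfg$scheduler_patience) {
          lr <- max(lr * train_cfg$scheduler_factor,
                    train_cfg$scheduler_min_lr)
          plateau <- 0L
        }
        if (stall >= train_cfg$early_stop_patience) break
      }
    }
    tt <- proc.time()[["elapsed"]] - t0
    fold_results[[f]] <- list(fold = f, history = hist,
                              best_state = best_state,
                              best_val_loss = best_val,
                              best_epoch = best_epoch,
                              val_patients = val_ids,
                              tt_seconds = tt)
  }
  structure(list(variant = variant$variant, folds = fold_results,
                 test_patients = split$test, model_cfg = model_cfg,
                 train_cfg = train_cfg, loss_cfg = loss_cfg),
            class = "cv_result")
}

# Slice-wise hybrid loss, matching the training objective exactly: the Dice
# term is computed per slice and averaged, focal/CE are means over pixels.
validation_loss <- function(model, va, batch_size, loss_cfg) {
  idx <- split(seq_len(va$n), ceiling(seq_len(va$n) / batch_size))
  tot <- 0
  for (ix in idx) {
    p <- predict_slices(model, va$x[, , , ix, drop = FALSE])
    g <- va$g[, , ix, drop = FALSE]
    for (k in seq_along(ix))
      tot <- tot + hybrid_loss(p[, , k], g[, , k], loss_cfg)
  }
  tot / va$n
}

#' @export
print.cv_result <- function(x, ...) {
  vals <- vapply(x$folds, `[[`, numeric(1), "best_val_loss")
  cat(sprintf("<cv_result> %s: %d folds, best val loss %.4f +/- %.4f\n",
              x$variant, length(x$folds), mean(vals), stats::sd(vals)))
  invisible(x)
}
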