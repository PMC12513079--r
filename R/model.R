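# R-side surface of the nested-UNet engine.

#' Nested-UNet model configuration
#'
#' Architecture of the 2D UNet++: 5 levels of conv-BN-ReLU double blocks
#' (3x3 kernels, stride 1), 2x2 max pooling, transposed-convolution
#' upsampling, dense in-level skip concatenations and a sigmoid 1x1 output
#' head. No dropout. Default filter widths `[16, 32, 64, 128, 256]`.
#'
#' @param levels Encoder depth.
#' @param filter_widths Integer vector of per-level channel widths; its
#'   length must equal `levels`.
#' @param in_channels Input channels (selected series per slice).
#' @return A `model_config`.
#' @export
model_config <- function(levels = 5L,
                         filter_widths = c(16L, 32L, 64L, 128L, 256L),
                         in_channels = 1L) {
  if (length(filter_widths) != levels)
    stop("configuration error: length(filter_widths) must equal levels")
  if (any(filter_widths < 1) || in_channels < 1 || levels < 2)
    stop("configuration error: widths, channels and levels must be positive")
  structure(list(levels = as.integer(levels),
                 filter_widths = as.integer(filter_widths),
                 in_channels = as.integer(in_channels),
                 conv_kernel = 3L, pool = "max 2x2",
                 upsample = "transposed convolution",
                 normalization = "batch", activation_hidden = "relu",
                 activation_out = "sigmoid", dropout = 0),
            class = "model_config")
}

#' Build a nested-UNet model
#'
#' Instantiates the network and reports its learnable parameter count.
#' Weight initialization draws from R's RNG, so `set.seed()` makes builds
#' reproducible.
#'
#' @param cfg A [model_config()].
#' @param quiet Suppress the parameter-count message.
#' @return A `unetpp_model` handle with `param_count`.
#' @export
build_model <- function(cfg = model_config(), quiet = FALSE) {
  ptr <- .unetpp_create(cfg$filter_widths, cfg$in_channels)
  n <- .unetpp_param_count(ptr)
  if (!quiet)
    message(sprintf("built UNet++ (%d levels, widths %s): %s parameters",
                    cfg$levels, paste(cfg$filter_widths, collapse = "/"),
                    format(n, big.mark = ",")))
  structure(list(ptr = ptr, config = cfg, param_count = n),
            class = "unetpp_model")
}

#' @export
print.unetpp_model <- function(x, ...) {
  cat(sprintf("<unetpp_model> %d levels, widths %s, %s parameters\n",
              x$config$levels,
              paste(x$config$filter_widths, collapse = "/"),
              format(x$param_count, big.mark = ",")))
  invisible(x)
}

check_input_shape <- function(model, h, w) {
  div <- 2^(model$config$levels - 1)
  if (h %% div != 0 || w %% div != 0)
    stop("shape error: input ", h, "x", w, " is not divisible by ", div,
         "; pad the in-plane shape to a multiple of ", div)
}

#' Forward pass on a slice batch
#'
#' @param model A [build_model()] handle.
#' @param x Array `(H, W, C, B)`; `H` and `W` must be divisible by
#'   `2^(levels - 1)`.
#' @return Probability array `(H, W, B)` with values in `[0, 1]`.
#' @export
predict_slices <- function(model, x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d[1:2], 1L, d[3])
  d <- dim(x)
  check_input_shape(model, d[1], d[2])
  if (d[3] != model$config$in_channels)
    stop("shape error: expected ", model$config$in_channels,
         " input channels, got ", d[3])
  .unetpp_forward(model$ptr, x, FALSE)
}

#' Extract / restore model state
#'
#' Weights plus batch-normalization running statistics, as a plain list of
#' numeric vectors (suitable for an RDS checkpoint with a JSON sidecar).
#'
#' @param model A `unetpp_model`.
#' @return Named list of numeric vectors.
#' @export
model_state <- function(model) .unetpp_get_state(model$ptr)

#' @rdname model_state
#' @param state A list previously returned by [model_state()].
#' @export
set_model_state <- function(model, state) {
  .unetpp_set_state(model$ptr, state)
  invisible(model)
}

# Per-volume min-max normalization to [0, 1]; constant volumes become 0.
normalize_volume <- function(arr) {
  rng <- range(arr)
  if (rng[2] - rng[1] <= 0) return(array(0, dim = dim(arr)))
  (arr - rng[1]) / (rng[2] - rng[1])
}

# (H, W, C, Z) slice stack for one variant patient under a channel selection.
patient_slice_stack <- function(patient, channels = "SUBTRACTION",
                                normalize = TRUE) {
  key <- tolower(channels)
  missing <- setdiff(key, names(patient$images))
  if (length(missing))
    stop("channel(s) ", paste(missing, collapse = ", "),
         " not present for patient ", patient$patient_id)
  d <- dim(patient$images[[key[1]]]$voxels)
  x <- array(0, dim = c(d[1], d[2], length(key), d[3]))
  for (ci in seq_along(key)) {
    v <- patient$images[[key[ci]]]$voxels
    if (normalize) v <- normalize_volume(v)
    x[, , ci, ] <- v
  }
  x
}

#' Predict lesion probabilities for one patient
#'
#' Runs the model slice-by-slice and reassembles a probability volume.
#'
#' @param model A `unetpp_model`.
#' @param patient One element of a `dataset_variant`'s `patients` list.
#' @param channels Series used as input channels.
#' @param normalize Min-max normalize each input volume.
#' @param batch_size Slices per forward batch.
#' @return Array `(H, W, Z)` of probabilities.
#' @export
predict_patient <- function(model, patient, channels = "SUBTRACTION",
                            normalize = TRUE, batch_size = 8L) {
  x <- patient_slice_stack(patient, channels, normalize)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], d[4]))
  idx <- split(seq_len(d[4]), ceiling(seq_len(d[4]) / batch_size))
  for (ix in idx)
    out[, , ix] <- predict_slices(model, x[, , , ix, drop = FALSE])
  out
}
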