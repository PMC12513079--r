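# Hybrid segmentation loss: weighted sum of soft Dice, focal and binary
# cross-entropy terms. These R implementations are the package's reference
# definitions; the training engine computes the same quantities natively.

#' Hybrid loss configuration
#'
#' Weights of the Dice, focal and cross-entropy terms (they must sum to 1;
#' study defaults 0.1 / 0.45 / 0.45) and the focal-loss parameters: the
#' balancing factor `alpha_t` and the focusing exponent `gamma_f`.
#'
#' @param alpha Dice-term weight.
#' @param beta Focal-term weight.
#' @param gamma_w Cross-entropy-term weight.
#' @param focal_alpha_t Focal balancing factor (default 0.25).
#' @param focal_gamma_f Focal focusing parameter (default 2).
#' @return A `hybrid_loss_config`.
#' @export
hybrid_loss_config <- function(alpha = 0.1, beta = 0.45, gamma_w = 0.45,
                               focal_alpha_t = 0.25, focal_gamma_f = 2) {
  if (alpha < 0 || beta < 0 || gamma_w < 0)
    stop("configuration error: loss weights must be non-negative")
  if (abs(alpha + beta + gamma_w - 1) > 1e-8)
    stop("configuration error: loss weights must sum to 1 (got ",
         alpha + beta + gamma_w, ")")
  structure(list(alpha = alpha, beta = beta, gamma_w = gamma_w,
                 focal_alpha_t = focal_alpha_t,
                 focal_gamma_f = focal_gamma_f),
            class = "hybrid_loss_config")
}

check_pred_target <- function(p, g) {
  if (!identical(dim(p), dim(g)) || length(p) != length(g))
    stop("alignment error: prediction and target shapes differ")
  if (any(p < 0 | p > 1)) stop("predictions must lie in [0, 1]")
}

#' Soft Dice loss
#'
#' `1 - (2 sum(P G) + eps) / (sum(P) + sum(G) + eps)`: one minus the soft
#' overlap between prediction and ground truth, with a smoothing epsilon for
#' empty masks.
#'
#' @param p Prediction array in `[0, 1]`.
#' @param g Binary ground-truth array of the same shape.
#' @param eps Smoothing epsilon.
#' @return Scalar loss.
#' @export
dice_loss <- function(p, g, eps = 1e-6) {
  check_pred_target(p, g)
  1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
}

#' Focal loss
#'
#' Mean over pixels of `-alpha_t (1 - p_t)^gamma_f log(p_t)` with
#' `p_t = P` where `G = 1` and `1 - P` where `G = 0`; predictions are
#' clipped away from 0 and 1 before the logarithm. Down-weights
#' well-classified pixels to counter the extreme foreground/background
#' imbalance of lesion masks.
#'
#' @param p,g As in [dice_loss()].
#' @param alpha_t Balancing factor.
#' @param gamma_f Focusing parameter (`gamma_f = 0`, `alpha_t = 1` recovers
#'   cross-entropy).
#' @param clip Clipping epsilon for the logarithm.
#' @return Scalar loss.
#' @export
focal_loss <- function(p, g, alpha_t = 0.25, gamma_f = 2, clip = 1e-7) {
  check_pred_target(p, g)
  p <- pmin(pmax(p, clip), 1 - clip)
  pt <- ifelse(g == 1, p, 1 - p)
  mean(-alpha_t * (1 - pt)^gamma_f * log(pt))
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-(G log P + (1 - G) log(1 - P))` (the standard
#' two-term binary form). `literal = TRUE` keeps only the foreground term
#' `-G log P`.
#'
#' @param p,g As in [dice_loss()].
#' @param clip Clipping epsilon for the logarithm.
#' @param literal Use the foreground-only single-term form.
#' @return Scalar loss.
#' @export
ce_loss <- function(p, g, clip = 1e-7, literal = FALSE) {
  check_pred_target(p, g)
  p <- pmin(pmax(p, clip), 1 - clip)
  if (literal) mean(-g * log(p))
  else mean(-(g * log(p) + (1 - g) * log(1 - p)))
}

#' Hybrid loss
#'
#' `alpha * Dice + beta * Focal + gamma * CrossEntropy` with the constraint
#' `alpha + beta + gamma = 1`.
#'
#' @param p,g As in [dice_loss()].
#' @param cfg A [hybrid_loss_config()].
#' @return Scalar loss.
#' @export
hybrid_loss <- function(p, g, cfg = hybrid_loss_config()) {
  if (!inherits(cfg, "hybrid_loss_config"))
    stop("configuration error: `cfg` must be a hybrid_loss_config")
  cfg$alpha * dice_loss(p, g) +
    cfg$beta * focal_loss(p, g, cfg$focal_alpha_t, cfg$focal_gamma_f) +
    cfg$gamma_w * ce_loss(p, g)
}
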