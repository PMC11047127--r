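# Combined Dice + categorical focal training loss.
#
# Both losses see a one-hot ground truth G and a probability map P with a
# trailing class axis; every voxel's probabilities sum to 1. The Dice term is
# the weighted multi-class soft Dice:
#
#   L_dice = 1 - (2 * sum_c sum_i w_c G_ci P_ci + eps) /
#                (sum_c sum_i w_c G_ci + sum_c sum_i w_c P_ci + eps)
#
# and the focal term is
#
#   L_focal = - sum_c sum_i G_ci * log(P_ci) * (1 - P_ci)^gamma
#
# summed over voxels as written (a voxel-mean variant is available via
# `reduce = "mean"`). gamma = 0 recovers categorical cross-entropy.

#' Loss configuration
#'
#' @param gamma Focal modulation exponent (>= 0); 1 by default, 0 gives plain
#'   categorical cross-entropy.
#' @param eps Small constant guarding the Dice denominator.
#' @param class_weights Optional non-negative weight per class for the Dice
#'   term; `NULL` means equal weights.
#' @param clip Probabilities are clipped to `[clip, 1 - clip]` before
#'   logarithms so the focal term stays finite.
#' @param focal_reduce `"sum"` (as defined) or `"mean"` over voxels.
#' @return A list of class `afms_loss_config`.
#' @export
loss_config <- function(gamma = 1, eps = 1e-5, class_weights = NULL,
                        clip = 1e-7, focal_reduce = c("sum", "mean")) {
  if (gamma < 0) abort_validation("gamma must be >= 0")
  if (eps <= 0) abort_validation("eps must be > 0")
  if (!is.null(class_weights) && any(class_weights < 0))
    abort_validation("class weights must be non-negative")
  structure(list(gamma = gamma, eps = eps, class_weights = class_weights,
                 clip = clip, focal_reduce = match.arg(focal_reduce)),
            class = "afms_loss_config")
}

as_gp <- function(truth, prob) {
  if (!identical(dim(truth), dim(prob)))
    abort_validation("truth and prob must have identical shapes")
  nd <- length(dim(truth))
  C <- dim(truth)[nd]
  list(G = matrix(truth, ncol = C), P = matrix(prob, ncol = C), C = C)
}

loss_weights <- function(cfg, C) {
  w <- cfg$class_weights
  if (is.null(w)) w <- rep(1, C)
  if (length(w) != C) abort_validation("class_weights length must equal the class count")
  w
}

#' Multi-class soft Dice loss
#'
#' @param truth One-hot ground truth array; last axis indexes classes.
#' @param prob Predicted probability array, congruent with `truth`.
#' @param cfg A [loss_config()].
#' @return Scalar in `[0, 1]`; 0 for a perfect hard prediction.
#' @export
dice_loss <- function(truth, prob, cfg = loss_config()) {
  gp <- as_gp(truth, prob)
  w <- loss_weights(cfg, gp$C)
  wG <- sweep(gp$G, 2, w, `*`)
  num <- 2 * sum(wG * gp$P) + cfg$eps
  den <- sum(wG) + sum(sweep(gp$P, 2, w, `*`)) + cfg$eps
  1 - num / den
}

# d(dice_loss)/dP, same shape as prob.
dice_loss_grad <- function(truth, prob, cfg = loss_config()) {
  gp <- as_gp(truth, prob)
  w <- loss_weights(cfg, gp$C)
  wG <- sweep(gp$G, 2, w, `*`)
  wP <- sweep(gp$P, 2, w, `*`)
  num <- 2 * sum(wG * gp$P) + cfg$eps
  den <- sum(wG) + sum(wP) + cfg$eps
  g <- -(2 * wG * den - num * rep(w, each = nrow(gp$G))) / den^2
  array(g, dim(prob))
}

#' Categorical focal loss
#'
#' @inheritParams dice_loss
#' @return Non-negative scalar; 0 for a perfect hard prediction.
#' @export
focal_loss <- function(truth, prob, cfg = loss_config()) {
  gp <- as_gp(truth, prob)
  p <- pmin(pmax(gp$P, cfg$clip), 1 - cfg$clip)
  v <- -sum(gp$G * log(p) * (1 - p)^cfg$gamma)
  if (cfg$focal_reduce == "mean") v <- v / nrow(gp$G)
  v
}

focal_loss_grad <- function(truth, prob, cfg = loss_config()) {
  gp <- as_gp(truth, prob)
  p <- pmin(pmax(gp$P, cfg$clip), 1 - cfg$clip)
  inside <- (gp$P > cfg$clip) & (gp$P < 1 - cfg$clip)
  # d/dp [ -G log(p) (1-p)^g ] = -G [ (1-p)^g / p - g (1-p)^(g-1) log(p) ]
  g <- -gp$G * ((1 - p)^cfg$gamma / p - cfg$gamma * (1 - p)^(cfg$gamma - 1) * log(p))
  g <- g * inside
  if (cfg$focal_reduce == "mean") g <- g / nrow(gp$G)
  array(g, dim(prob))
}

#' Total training loss: Dice + focal
#'
#' @inheritParams dice_loss
#' @return `dice_loss(...) + focal_loss(...)`, exactly.
#' @export
total_loss <- function(truth, prob, cfg = loss_config()) {
  dice_loss(truth, prob, cfg) + focal_loss(truth, prob, cfg)
}

total_loss_grad <- function(truth, prob, cfg = loss_config()) {
  dice_loss_grad(truth, prob, cfg) + focal_loss_grad(truth, prob, cfg)
}
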