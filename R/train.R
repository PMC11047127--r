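# Training driver: Adam with an L2 weight penalty on the total
# (Dice + focal) loss, whole-volume batches, validation-selected checkpoint.

adam_new <- function(flat) {
  list(m = lapply(flat, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(flat, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(state, flat, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] - lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, flat = flat)
}

unflatten_params <- function(nested, flat) {
  for (nm in names(flat)) nested <- set_param(nested, nm, flat[[nm]])
  nested
}

# Convert a labeled record to a training pair (5-axis input, one-hot truth).
record_to_pair <- function(rec, n_classes, label_values = NULL) {
  img <- rec$image
  x <- array(img, c(1L, dim(img)))
  if (is.null(rec$labels)) abort_validation(sprintf("record '%s' has no labels", rec$id))
  oh <- one_hot_labels(rec$labels, label_values = label_values, n_classes = n_classes)
  g <- array(oh, c(1L, dim(oh)))
  list(x = x, g = g)
}

# Mean foreground Dice of a probability map against one-hot truth at 0.5.
prob_dsc <- function(prob, onehot) {
  K <- dim(prob)[length(dim(prob))]
  pm <- matrix(prob, ncol = K)
  gm <- matrix(onehot, ncol = K)
  vals <- vapply(2:K, function(k) {
    om <- overlap_metrics(confusion_counts(pm[, k] >= 0.5, gm[, k] > 0.5))
    om$dsc
  }, numeric(1))
  mean(vals)
}

#' Train a segmentation network
#'
#' Minimizes the combined Dice + focal loss with Adam (default learning rate
#' 1e-4) plus an L2 weight penalty `weight_decay * sum(W^2)` over convolution
#' kernels (biases and batch-norm parameters are exempt). Batches are whole
#' volumes (batch size 1). The checkpoint with the lowest validation loss is
#' retained; training stops early after `patience` epochs without validation
#' improvement, or as soon as the mean training DSC reaches `target_dsc`.
#'
#' @param net An [build_network()] network (modified copy returned).
#' @param train_records List of labeled `afms_volume` records whose label
#'   values are already contiguous `0..K-1`.
#' @param val_records Optional validation records.
#' @param epochs Maximum number of epochs (>= 1).
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty coefficient.
#' @param loss A [loss_config()].
#' @param patience Early-stopping patience on validation loss.
#' @param target_dsc Optional training-DSC early-stop target in `(0, 1]`.
#' @param time_budget Optional wall-clock budget in seconds; training stops
#'   after the first epoch that exceeds it.
#' @param verbose Print per-epoch progress.
#' @return The trained network, with a `history` attribute: a tibble of class
#'   `afms_history` (epoch, train_loss, train_dsc, val_loss, val_dsc).
#' @export
train_network <- function(net, train_records, val_records = NULL, epochs = 100L,
                          lr = 1e-4, weight_decay = 5e-4, loss = loss_config(),
                          patience = 20L, target_dsc = NULL, time_budget = NULL,
                          verbose = FALSE) {
  t_start <- Sys.time()
  if (epochs < 1) abort_validation("epochs must be >= 1")
  if (lr <= 0) abort_validation("learning rate must be > 0")
  if (weight_decay < 0) abort_validation("weight_decay must be >= 0")
  K <- net$spec$n_classes
  pairs <- lapply(train_records, record_to_pair, n_classes = K,
                  label_values = 0:(K - 1))
  vpairs <- if (!is.null(val_records))
    lapply(val_records, record_to_pair, n_classes = K, label_values = 0:(K - 1))
  flat <- flatten_params(net$params)
  decayed <- grepl("\\.W$", names(flat)) & !grepl("(gamma|beta)$", names(flat))
  opt <- adam_new(flat)
  hist <- list()
  best_val <- Inf
  best <- NULL
  stale <- 0L
  for (ep in seq_len(epochs)) {
    tl <- td <- 0
    for (pr in pairs) {
      tape <- new_tape()
      fw <- net_forward(net, pr$x, training = TRUE, tape = tape)
      P <- tape$nodes[[fw$out]]$val
      lv <- total_loss(pr$g, P, loss)
      if (!is.finite(lv)) abort_afms("training loss is not finite; aborting", "afms_numeric_error")
      seed_grad <- total_loss_grad(pr$g, P, loss)
      grads_all <- tp_backward(tape, fw$out, seed_grad)
      grads <- list()
      for (nm in names(fw$leafmap$ids)) grads[[nm]] <- grads_all[[fw$leafmap$ids[[nm]]]]
      for (nm in names(flat)[decayed]) {
        g <- grads[[nm]] %||% 0
        grads[[nm]] <- g + 2 * weight_decay * flat[[nm]]
      }
      st <- adam_step(opt, flat, grads, lr)
      opt <- st$state
      flat <- st$flat
      net$params <- unflatten_params(net$params, flat)
      tl <- tl + lv
      td <- td + prob_dsc(P, pr$g)
    }
    tl <- tl / length(pairs); td <- td / length(pairs)
    vl <- vd <- NA_real_
    if (!is.null(vpairs)) {
      vl <- vd <- 0
      for (pr in vpairs) {
        P <- net_forward(net, pr$x, training = FALSE)
        vl <- vl + total_loss(pr$g, P, loss)
        vd <- vd + prob_dsc(P, pr$g)
      }
      vl <- vl / length(vpairs); vd <- vd / length(vpairs)
      if (vl < best_val) {
        best_val <- vl
        best <- list(params = net$params, bn = as.list(net$bn_state))
        stale <- 0L
      } else stale <- stale + 1L
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = tl, train_dsc = td,
                                 val_loss = vl, val_dsc = vd)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  dsc %.4f%s", ep, tl, td,
                      if (is.na(vl)) "" else sprintf("  val_loss %.4f  val_dsc %.4f", vl, vd)))
    if (!is.null(target_dsc) && td >= target_dsc) break
    if (!is.null(vpairs) && stale >= patience) break
    if (!is.null(time_budget) &&
        as.numeric(difftime(Sys.time(), t_start, units = "secs")) > time_budget) break
  }
  if (!is.null(best)) {
    net$params <- best$params
    bn <- new.env(parent = emptyenv())
    for (nm in names(best$bn)) bn[[nm]] <- best$bn[[nm]]
    net$bn_state <- bn
  }
  history <- do.call(rbind, hist)
  class(history) <- c("afms_history", class(history))
  attr(net, "history") <- history
  net
}

#' Plot a training history
#'
#' @param object An `afms_history` tibble (the `history` attribute of a
#'   trained network).
#' @param ... Unused.
#' @return A ggplot of loss and DSC curves over epochs.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.afms_history <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  long <- rbind(
    data.frame(epoch = df$epoch, value = df$train_loss, metric = "loss", split = "train"),
    data.frame(epoch = df$epoch, value = df$train_dsc, metric = "dsc", split = "train"),
    data.frame(epoch = df$epoch, value = df$val_loss, metric = "loss", split = "validation"),
    data.frame(epoch = df$epoch, value = df$val_dsc, metric = "dsc", split = "validation"))
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Predict a segmentation for one volume
#'
#' Runs an inference forward pass (running batch-norm statistics) and returns
#' the per-voxel class probabilities and the hard label map (argmax), with
#' class indices mapped back to the raw labeling scheme.
#'
#' @param net A trained `afms_network`.
#' @param volume An `afms_volume` or a `(H, W, D, C)` array.
#' @param label_values Raw label value per class index (default `0..K-1`).
#' @return List with `prob` `(H, W, D, K)` and `labels` `(H, W, D)`.
#' @export
predict_volume <- function(net, volume, label_values = NULL) {
  img <- if (inherits(volume, "afms_volume")) volume$image else volume
  if (length(dim(img)) == 3L) dim(img) <- c(dim(img), 1L)
  x <- array(img, c(1L, dim(img)))
  P <- net_forward(net, x, training = FALSE)
  d <- dim(P)
  prob <- array(P[1, , , , ], d[2:5])
  K <- d[5]
  if (is.null(label_values)) label_values <- 0:(K - 1)
  pm <- matrix(prob, ncol = K)
  hard <- label_values[max.col(pm, ties.method = "first")]
  list(prob = prob, labels = array(as.integer(hard), d[2:4]))
}

#' Evaluate a network over a labeled dataset
#'
#' Predicts every record and accumulates per-case metrics reports, plus macro
#' (mean and sd over cases) and micro (pooled confusion counts) aggregates.
#'
#' @param net A trained `afms_network`.
#' @param records Labeled `afms_volume` records with contiguous labels.
#' @param regions Optional region definitions for [region_binary_masks()].
#' @param spacing Voxel spacing for AHD (mm per axis).
#' @return List: `per_case` tibble (one row per case x class/region),
#'   `macro` tibble (mean and sd per unit), `micro` tibble (pooled counts).
#' @export
evaluate_network <- function(net, records, regions = NULL, spacing = c(1, 1, 1)) {
  if (any(vapply(records, function(r) is.null(r$labels), logical(1))))
    abort_validation("every record must have labels")
  per <- lapply(records, function(rec) {
    pred <- predict_volume(net, rec)
    rep_ <- metrics_report(pred$labels, rec$labels, regions = regions,
                           spacing = spacing)
    tibble::tibble(id = rec$id, tibble::as_tibble(unclass(rep_)))
  })
  per_case <- do.call(rbind, per)
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  units <- unique(per_case$unit)
  macro <- do.call(rbind, lapply(units, function(u) {
    sub <- per_case[per_case$unit == u, ]
    tibble::tibble(unit = u,
                   dsc_mean = mean(sub$dsc), dsc_sd = stats::sd(sub$dsc),
                   iou_mean = mean(sub$iou), iou_sd = stats::sd(sub$iou),
                   accuracy_mean = mean(sub$accuracy),
                   precision_mean = mean(sub$precision),
                   recall_mean = mean(sub$recall),
                   ahd_mean = mean(sub$ahd[is.finite(sub$ahd)]))
  }))
  micro <- do.call(rbind, lapply(units, function(u) {
    sub <- per_case[per_case$unit == u, ]
    cc <- list(tp = sum(sub$tp), tn = sum(sub$tn), fp = sum(sub$fp), fn = sum(sub$fn))
    tibble::tibble(unit = u, overlap_metrics(cc))
  }))
  list(per_case = per_case, macro = macro, micro = micro)
}
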