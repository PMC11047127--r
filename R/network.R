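#' Architectural hyperparameters for an encoder-decoder segmentation network
#'
#' Describes a volumetric encoder-decoder: `n_stages` attention encoder blocks
#' (SAEB or DAEB), each followed by 3x3x3 max pooling with stride 2; a
#' bottleneck block; SegPath refinement on every skip connection; a decoder of
#' transpose-convolution upsampling, skip concatenation and two 3x3x3
#' conv+BN+ReLU refinements per stage; and a 1x1x1 convolution head with a
#' per-voxel softmax over `n_classes` channels.
#'
#' @param variant `"SAEB"` or `"DAEB"` -- which encoder block to use.
#' @param n_stages Number of encoder stages (>= 2). Input spatial dimensions
#'   must be divisible by `2^n_stages`.
#' @param base_channels Channel width of the first stage.
#' @param channel_growth Width multiplier per stage (default 2).
#' @param se_reduction Squeeze-and-excitation reduction ratio `r`; every stage
#'   width must be divisible by it.
#' @param segpath_iterations Integer vector of SegPath iteration counts, one
#'   per skip level from shallowest to deepest (0 = plain skip). Recycled to
#'   `n_stages` if length 1. Default `4,3,2,1` for 4 stages: shallow skips
#'   carry the larger semantic gap and receive more refinement.
#' @param spatial_kernel Kernel size of the DAEB spatial-attention convolution.
#' @param n_classes Number of output classes `K` (including background).
#' @param input_channels Number of image channels (modalities).
#' @return An object of class `afms_spec`.
#' @export
network_spec <- function(variant = c("SAEB", "DAEB"), n_stages = 4L,
                         base_channels = 16L, channel_growth = 2,
                         se_reduction = 4L, segpath_iterations = NULL,
                         spatial_kernel = 7L, n_classes = 2L,
                         input_channels = 1L) {
  variant <- match.arg(variant)
  n_stages <- as.integer(n_stages)
  if (n_stages < 2L) abort_config("n_stages must be >= 2")
  if (base_channels < 1L) abort_config("base_channels must be >= 1")
  if (se_reduction < 1L) abort_config("se_reduction must be >= 1")
  if (n_classes < 2L) abort_config("n_classes must be >= 2")
  if (spatial_kernel %% 2 == 0) abort_config("spatial_kernel must be odd")
  if (is.null(segpath_iterations))
    segpath_iterations <- rev(seq_len(n_stages))
  if (length(segpath_iterations) == 1L)
    segpath_iterations <- rep(segpath_iterations, n_stages)
  if (length(segpath_iterations) != n_stages)
    abort_config("segpath_iterations must have one entry per encoder stage")
  if (any(segpath_iterations < 0)) abort_config("segpath_iterations must be >= 0")
  widths <- as.integer(round(base_channels * channel_growth^(0:n_stages)))
  if (any(widths[seq_len(n_stages)] %% se_reduction != 0))
    abort_config("every stage width must be divisible by se_reduction")
  structure(list(variant = variant, n_stages = n_stages,
                 base_channels = as.integer(base_channels),
                 channel_growth = channel_growth,
                 se_reduction = as.integer(se_reduction),
                 segpath_iterations = as.integer(segpath_iterations),
                 spatial_kernel = as.integer(spatial_kernel),
                 n_classes = as.integer(n_classes),
                 input_channels = as.integer(input_channels),
                 widths = widths),
            class = "afms_spec")
}

init_block_params <- function(spec, cin, cout) {
  if (spec$variant == "SAEB") init_saeb_params(cin, cout, spec$se_reduction)
  else init_daeb_params(cin, cout, spec$se_reduction, spec$spatial_kernel)
}

#' Build a segmentation network
#'
#' All parameters (He-uniform convolution kernels, zero biases, unit/zero
#' batch-norm scale/shift) are drawn deterministically from `seed`: two builds
#' with the same spec and seed are bit-identical.
#'
#' @param spec An [network_spec()] object.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `afms_network` holding the spec, a nested
#'   parameter list, and an environment of batch-norm running statistics.
#' @export
build_network <- function(spec, seed = 1L) {
  if (!inherits(spec, "afms_spec")) abort_config("spec must be an afms_spec")
  w <- spec$widths
  n <- spec$n_stages
  params <- withr::with_seed(as.integer(seed), {
    p <- list()
    cin <- spec$input_channels
    for (s in seq_len(n)) {
      p[[sprintf("enc%d", s)]] <- init_block_params(spec, cin, w[s])
      cin <- w[s]
    }
    p$bottleneck <- init_block_params(spec, w[n], w[n + 1])
    for (s in seq_len(n)) {
      it <- spec$segpath_iterations[s]
      if (it > 0) p[[sprintf("skip%d", s)]] <- init_segpath_params(w[s], it)
    }
    cur <- w[n + 1]
    for (s in rev(seq_len(n))) {
      p[[sprintf("dec%d", s)]] <- list(
        up = list(W = he_uniform(c(2, 2, 2, cur, w[s]), 8 * cur), b = numeric(w[s])),
        c1 = conv_init(3L, 2L * w[s], w[s]), bn1 = bn_init(w[s]),
        c2 = conv_init(3L, w[s], w[s]), bn2 = bn_init(w[s]))
      cur <- w[s]
    }
    p$head <- conv_init(1L, w[1], spec$n_classes)
    p
  })
  structure(list(spec = spec, params = params,
                 bn_state = new.env(parent = emptyenv())),
            class = "afms_network")
}

# Flatten/unflatten the nested parameter list for the optimizer.
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

set_param <- function(p, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  assign_rec <- function(lst, parts, value) {
    if (length(parts) == 1L) { lst[[parts]] <- value; return(lst) }
    lst[[parts[1]]] <- assign_rec(lst[[parts[1]]], parts[-1], value)
    lst
  }
  assign_rec(p, parts, value)
}

# Forward pass shared by inference and training. With a tape, returns
# list(tape, out = node id, leafmap); without, returns the probability array.
net_forward <- function(net, x, training = FALSE, tape = NULL) {
  spec <- net$spec
  check_feature_map(x)
  d <- dim(x)
  if (d[5] != spec$input_channels)
    abort_validation(sprintf("input has %d channels; the network expects %d",
                             d[5], spec$input_channels))
  div <- 2^spec$n_stages
  if (any(d[2:4] %% div != 0))
    abort_validation(sprintf(
      "input spatial dimensions (%s) must each be divisible by 2^n_stages = %d",
      paste(d[2:4], collapse = "x"), div))
  flat <- flatten_params(net$params)
  leafmap <- if (!is.null(tape)) {
    e <- new.env(parent = emptyenv()); e$ids <- list(); e
  } else NULL
  Pfor <- function(block) {
    force(block)
    function(name) {
      key <- paste0(block, ".", name)
      v <- flat[[key]]
      if (is.null(v)) abort_config(sprintf("missing parameter '%s'", key))
      if (is.null(tape)) return(v)
      id <- leafmap$ids[[key]]
      if (is.null(id)) {
        id <- tp_leaf(tape, v)
        leafmap$ids[[key]] <- id
      }
      id
    }
  }
  state <- net$bn_state
  cur <- if (is.null(tape)) x else tp_leaf(tape, x)
  skips <- vector("list", spec$n_stages)
  for (s in seq_len(spec$n_stages)) {
    key <- sprintf("enc%d", s)
    cur <- if (spec$variant == "SAEB")
      block_saeb(tape, cur, Pfor(key), state, key, training)
    else block_daeb(tape, cur, Pfor(key))
    skips[[s]] <- cur
    cur <- tp_maxpool3d(tape, cur)
  }
  cur <- if (spec$variant == "SAEB")
    block_saeb(tape, cur, Pfor("bottleneck"), state, "bottleneck", training)
  else block_daeb(tape, cur, Pfor("bottleneck"))
  for (s in rev(seq_len(spec$n_stages))) {
    dk <- sprintf("dec%d", s)
    P <- Pfor(dk)
    cur <- tp_upconv3d(tape, cur, P("up.W"), P("up.b"))
    it <- spec$segpath_iterations[s]
    sk <- if (it > 0)
      block_segpath(tape, skips[[s]], Pfor(sprintf("skip%d", s)), it, state,
                    sprintf("skip%d", s), training)
    else skips[[s]]
    cur <- tp_concat_c(tape, cur, sk)
    cur <- tp_relu(tape, tp_bn(tape, tp_conv3d(tape, cur, P("c1.W"), P("c1.b")),
                               P("bn1.gamma"), P("bn1.beta"), state,
                               paste0(dk, ".bn1"), training))
    cur <- tp_relu(tape, tp_bn(tape, tp_conv3d(tape, cur, P("c2.W"), P("c2.b")),
                               P("bn2.gamma"), P("bn2.beta"), state,
                               paste0(dk, ".bn2"), training))
  }
  Ph <- Pfor("head")
  cur <- tp_conv3d(tape, cur, Ph("W"), Ph("b"))
  out <- tp_softmax_c(tape, cur)
  if (is.null(tape)) return(out)
  list(tape = tape, out = out, leafmap = leafmap)
}

#' Run a forward pass through a built network
#'
#' @param net An [build_network()] result.
#' @param x Input feature map `(batch, H, W, D, input_channels)`; spatial
#'   dimensions must be divisible by `2^n_stages`.
#' @param training Use batch statistics (`TRUE`) or running statistics in the
#'   batch-norm layers.
#' @return Probability map `(batch, H, W, D, n_classes)`; voxelwise softmax,
#'   channels sum to 1.
#' @export
network_forward <- function(net, x, training = FALSE) {
  if (!inherits(net, "afms_network")) abort_config("net must be an afms_network")
  net_forward(net, x, training = training, tape = NULL)
}

#' Count trainable parameters
#'
#' Counts every scalar in the network's convolution kernels, biases and
#' batch-norm scale/shift vectors.
#'
#' @param net An `afms_network` or an `afms_spec` (which is built with a
#'   throwaway seed just to count).
#' @return Integer scalar.
#' @export
count_parameters <- function(net) {
  if (inherits(net, "afms_spec")) net <- build_network(net, seed = 0L)
  if (!inherits(net, "afms_network")) abort_config("net must be an afms_network or afms_spec")
  sum(vapply(flatten_params(net$params), length, numeric(1)))
}

#' @export
print.afms_spec <- function(x, ...) {
  cat(sprintf("<afms_spec> %s, %d stages, widths %s, K=%d, in=%d, segpath=[%s]\n",
              x$variant, x$n_stages, paste(x$widths, collapse = "/"),
              x$n_classes, x$input_channels,
              paste(x$segpath_iterations, collapse = ",")))
  invisible(x)
}

#' @export
print.afms_network <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  trainable parameters: %d\n", count_parameters(x)))
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.afms_network <- function(x, ...) {
  tibble::tibble(variant = x$spec$variant, n_stages = x$spec$n_stages,
                 base_channels = x$spec$base_channels,
                 n_classes = x$spec$n_classes,
                 n_parameters = count_parameters(x))
}

#' Save / load a network checkpoint
#'
#' The checkpoint is self-describing: it stores the architectural spec next to
#' the parameters and batch-norm running statistics, so [load_checkpoint()]
#' needs nothing else.
#'
#' @param net An `afms_network`.
#' @param path File path (`.rds`).
#' @param history Optional training-history tibble stored alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path, history = NULL) {
  obj <- list(spec = unclass(net$spec), params = net$params,
              bn_state = as.list(net$bn_state), history = history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("checkpoint not found: %s", path))
  obj <- readRDS(path)
  bn <- new.env(parent = emptyenv())
  for (nm in names(obj$bn_state)) bn[[nm]] <- obj$bn_state[[nm]]
  net <- structure(list(spec = structure(obj$spec, class = "afms_spec"),
                        params = obj$params, bn_state = bn),
                   class = "afms_network")
  attr(net, "history") <- obj$history
  net
}
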