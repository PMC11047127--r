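# Reverse-mode automatic differentiation over dense 5-axis tensors.
#
# A tape records one forward pass as a flat list of nodes; tp_backward() walks
# it in reverse, accumulating gradients. Every tp_* operation also works with
# tape = NULL, in which case its arguments are plain arrays and it simply
# returns the forward value -- the same code path serves inference and the
# standalone block functions.
#
# Tensor axis order is (batch, H, W, D, channel) throughout.

new_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

# NB: force x before touching tape$nodes -- evaluating x may itself emit
# nodes (parameter leaves are created lazily inside argument promises).
tval <- function(tape, x) {
  force(x)
  if (is.null(tape)) x else tape$nodes[[x]]$val
}

emit <- function(tape, val, parents, bwd, cache = NULL) {
  if (is.null(tape)) return(val)
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- list(val = val, parents = as.integer(parents), bwd = bwd, cache = cache)
  tape$n <- n
  n
}

tp_leaf <- function(tape, val) {
  if (is.null(tape)) return(val)
  emit(tape, val, integer(0), NULL)
}

#' @noRd
tp_backward <- function(tape, root, seed_grad) {
  grads <- vector("list", tape$n)
  grads[[root]] <- seed_grad
  for (i in seq(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || length(node$parents) == 0L) next
    pg <- node$bwd(g, node)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

# ---- shape helpers ---------------------------------------------------------

# Expand m (dims dm with 1s on broadcast axes) to full dims dx by index
# replication; inverse of reduce_to().
bcast_to <- function(m, dx) {
  dm <- dim(m)
  ix <- lapply(seq_along(dx), function(a) if (dm[a] == 1L) rep.int(1L, dx[a]) else seq_len(dx[a]))
  do.call(`[`, c(list(m), ix, list(drop = FALSE)))
}

# Sum v over axis ax, keeping a singleton dimension there.
sum_axis <- function(v, ax) {
  d <- dim(v)
  n1 <- prod(d[seq_len(ax - 1L)])
  n2 <- d[ax]
  n3 <- prod(d) / (n1 * n2)
  m <- array(v, c(n1, n2, n3))
  out <- colSums(aperm(m, c(2L, 1L, 3L)))
  d[ax] <- 1L
  array(out, d)
}

# Sum v down to target dims (1s where v must be collapsed).
reduce_to <- function(v, tdim) {
  d <- dim(v)
  for (ax in seq_along(d)) {
    if (tdim[ax] == 1L && dim(v)[ax] > 1L) v <- sum_axis(v, ax)
  }
  v
}

# ---- primitive ops ---------------------------------------------------------

tp_conv3d <- function(tape, x, w, b) {
  xv <- tval(tape, x); wv <- tval(tape, w); bv <- tval(tape, b)
  y <- conv3d_fwd_cpp(xv, dim(xv), wv, dim(wv), bv)
  emit(tape, y, c(x, w, b), function(g, node) {
    cc <- node$cache
    r <- conv3d_bwd_cpp(cc$x, dim(cc$x), cc$w, dim(cc$w), g)
    list(r$dx, r$dw, r$db)
  }, cache = list(x = xv, w = wv))
}

tp_upconv3d <- function(tape, x, w, b) {
  xv <- tval(tape, x); wv <- tval(tape, w); bv <- tval(tape, b)
  y <- upconv3d_fwd_cpp(xv, dim(xv), wv, bv)
  emit(tape, y, c(x, w, b), function(g, node) {
    cc <- node$cache
    r <- upconv3d_bwd_cpp(cc$x, dim(cc$x), cc$w, g)
    list(r$dx, r$dw, r$db)
  }, cache = list(x = xv, w = wv))
}

tp_maxpool3d <- function(tape, x) {
  xv <- tval(tape, x)
  r <- maxpool3d_fwd_cpp(xv, dim(xv))
  emit(tape, r$y, x, function(g, node) {
    list(maxpool3d_bwd_cpp(node$cache$argmax, g, node$cache$xdim))
  }, cache = list(argmax = r$argmax, xdim = dim(xv)))
}

tp_relu <- function(tape, x) {
  xv <- tval(tape, x)
  y <- xv * (xv > 0)
  emit(tape, y, x, function(g, node) list(g * node$cache), cache = (xv > 0))
}

tp_sigmoid <- function(tape, x) {
  xv <- tval(tape, x)
  y <- 1 / (1 + exp(-xv))
  emit(tape, y, x, function(g, node) list(g * node$cache * (1 - node$cache)), cache = y)
}

# Softmax over the channel axis, jointly per (batch, voxel).
tp_softmax_c <- function(tape, x) {
  xv <- tval(tape, x)
  d <- dim(xv); C <- d[5]
  m <- matrix(xv, ncol = C)
  mx <- m[, 1]
  if (C > 1) for (c in 2:C) mx <- pmax(mx, m[, c])
  e <- exp(m - mx)
  y <- e / rowSums(e)
  ya <- array(y, d)
  emit(tape, ya, x, function(g, node) {
    d <- node$cache$d
    ym <- matrix(node$cache$y, ncol = d[5])
    gm <- matrix(g, ncol = d[5])
    dx <- ym * (gm - rowSums(gm * ym))
    list(array(dx, d))
  }, cache = list(y = ya, d = d))
}

# Global average pooling over the spatial axes -> (b, 1, 1, 1, C).
tp_gap <- function(tape, x) {
  xv <- tval(tape, x)
  d <- dim(xv)
  y <- reduce_to(xv, c(d[1], 1L, 1L, 1L, d[5])) / prod(d[2:4])
  emit(tape, y, x, function(g, node) {
    d <- node$cache
    list(bcast_to(g / prod(d[2:4]), d))
  }, cache = d)
}

tp_add <- function(tape, a, b) {
  y <- tval(tape, a) + tval(tape, b)
  emit(tape, y, c(a, b), function(g, node) list(g, g))
}

# Elementwise product of x with a broadcastable map m (singleton axes expand).
tp_mul_bcast <- function(tape, x, m) {
  xv <- tval(tape, x); mv <- tval(tape, m)
  mf <- bcast_to(mv, dim(xv))
  y <- xv * mf
  emit(tape, y, c(x, m), function(g, node) {
    cc <- node$cache
    list(g * cc$mf, reduce_to(g * cc$x, cc$mdim))
  }, cache = list(x = xv, mf = mf, mdim = dim(mv)))
}

tp_concat_c <- function(tape, a, b) {
  av <- tval(tape, a); bv <- tval(tape, b)
  da <- dim(av); db_ <- dim(bv)
  y <- array(0, c(da[1:4], da[5] + db_[5]))
  y[, , , , seq_len(da[5])] <- av
  y[, , , , da[5] + seq_len(db_[5])] <- bv
  emit(tape, y, c(a, b), function(g, node) {
    ca <- node$cache
    list(g[, , , , seq_len(ca[1]), drop = FALSE],
         g[, , , , ca[1] + seq_len(ca[2]), drop = FALSE])
  }, cache = c(da[5], db_[5]))
}

# Max over channels -> (b,H,W,D,1); ties resolved to the lowest channel index.
tp_chan_max <- function(tape, x) {
  xv <- tval(tape, x)
  d <- dim(xv); C <- d[5]
  m <- matrix(xv, ncol = C)
  arg <- max.col(m, ties.method = "first")
  y <- array(m[cbind(seq_len(nrow(m)), arg)], c(d[1:4], 1L))
  emit(tape, y, x, function(g, node) {
    cc <- node$cache
    dm <- matrix(0, nrow = prod(cc$d[1:4]), ncol = cc$d[5])
    dm[cbind(seq_len(nrow(dm)), cc$arg)] <- as.vector(g)
    list(array(dm, cc$d))
  }, cache = list(arg = arg, d = d))
}

tp_chan_avg <- function(tape, x) {
  xv <- tval(tape, x)
  d <- dim(xv)
  y <- reduce_to(xv, c(d[1:4], 1L)) / d[5]
  emit(tape, y, x, function(g, node) {
    d <- node$cache
    list(bcast_to(g, d) / d[5])
  }, cache = d)
}

# Batch normalization per channel. In training mode the statistics are the
# batch mean and (biased) variance over all batch and spatial positions;
# running statistics in `state[[key]]` are updated as a side effect with
# momentum 0.9. In inference mode the stored running statistics are used.
tp_bn <- function(tape, x, gamma, beta, state = NULL, key = NULL,
                  training = TRUE, eps = 1e-5, momentum = 0.9) {
  xv <- tval(tape, x); gv <- tval(tape, gamma); bv <- tval(tape, beta)
  d <- dim(xv); C <- d[5]
  n <- prod(d[1:4])
  m <- matrix(xv, ncol = C)
  if (training || is.null(state) || is.null(state[[key]])) {
    mu <- colMeans(m)
    va <- colMeans(m^2) - mu^2
    va[va < 0] <- 0
    if (!is.null(state) && !is.null(key) && training) {
      prev <- state[[key]]
      if (is.null(prev)) state[[key]] <- list(mean = mu, var = va)
      else state[[key]] <- list(mean = momentum * prev$mean + (1 - momentum) * mu,
                                var  = momentum * prev$var  + (1 - momentum) * va)
    }
    batch_mode <- TRUE
  } else {
    mu <- state[[key]]$mean
    va <- state[[key]]$var
    batch_mode <- FALSE
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(m, 2, mu, `-`) * rep(inv, each = n)
  y <- sweep(sweep(xhat, 2, gv, `*`), 2, bv, `+`)
  emit(tape, array(y, d), c(x, gamma, beta), function(g, node) {
    cc <- node$cache
    gm <- matrix(g, ncol = cc$C)
    dgamma <- colSums(gm * cc$xhat)
    dbeta <- colSums(gm)
    if (cc$batch_mode) {
      # standard batch-statistics backward
      t1 <- sweep(gm, 2, colMeans(gm), `-`)
      t2 <- cc$xhat * rep(colMeans(gm * cc$xhat), each = cc$n)
      dx <- sweep(t1 - t2, 2, cc$gv * cc$inv, `*`)
    } else {
      dx <- sweep(gm, 2, cc$gv * cc$inv, `*`)
    }
    list(array(dx, cc$d), dgamma, dbeta)
  }, cache = list(xhat = xhat, inv = inv, gv = gv, d = d, C = C, n = n,
                  batch_mode = batch_mode))
}
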