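# Independent scalar-loop oracles for the encoder blocks, losses and
# distances. These deliberately share no code with the package internals:
# every operation is an explicit nested loop over voxels.

oracle_conv3d <- function(x, w, bias) {
  d <- dim(x); K <- dim(w)[1]; Ci <- dim(w)[4]; Co <- dim(w)[5]
  p <- (K - 1) / 2
  y <- array(0, c(d[1:4], Co))
  for (bb in 1:d[1]) for (i in 1:d[2]) for (j in 1:d[3]) for (k in 1:d[4])
    for (co in 1:Co) {
      acc <- bias[co]
      for (a in 1:K) for (q in 1:K) for (cc in 1:K) for (ci in 1:Ci) {
        ii <- i + a - 1 - p; jj <- j + q - 1 - p; kk <- k + cc - 1 - p
        if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3] && kk >= 1 && kk <= d[4])
          acc <- acc + x[bb, ii, jj, kk, ci] * w[a, q, cc, ci, co]
      }
      y[bb, i, j, k, co] <- acc
    }
  y
}

oracle_bn <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (c in 1:d[5]) {
    v <- as.vector(x[, , , , c])
    mu <- mean(v)
    va <- mean((v - mu)^2)
    y[, , , , c] <- gamma[c] * (x[, , , , c] - mu) / sqrt(va + eps) + beta[c]
  }
  y
}

# 1x1x1 convolution on a (b,1,1,1,C) descriptor = per-sample matrix product.
oracle_fc <- function(s, w, bias) {
  d <- dim(s); Ci <- dim(w)[4]; Co <- dim(w)[5]
  out <- array(0, c(d[1], 1, 1, 1, Co))
  for (bb in 1:d[1]) for (co in 1:Co) {
    acc <- bias[co]
    for (ci in 1:Ci) acc <- acc + s[bb, 1, 1, 1, ci] * w[1, 1, 1, ci, co]
    out[bb, 1, 1, 1, co] <- acc
  }
  out
}

oracle_gap <- function(x) {
  d <- dim(x)
  s <- array(0, c(d[1], 1, 1, 1, d[5]))
  for (bb in 1:d[1]) for (c in 1:d[5])
    s[bb, 1, 1, 1, c] <- mean(x[bb, , , , c])
  s
}

oracle_saeb <- function(x, p) {
  y <- oracle_conv3d(x, p$conv$W, p$conv$b)
  ybn <- oracle_bn(y, p$bn$gamma, p$bn$beta)
  s <- oracle_gap(ybn)
  z <- oracle_fc(s, p$fc1$W, p$fc1$b)
  z <- pmax(z, 0)
  z <- oracle_fc(z, p$fc2$W, p$fc2$b)
  d <- dim(ybn)
  out <- ybn
  for (bb in 1:d[1]) {
    e <- exp(z[bb, 1, 1, 1, ] - max(z[bb, 1, 1, 1, ]))
    a <- e / sum(e)
    for (c in 1:d[5]) out[bb, , , , c] <- ybn[bb, , , , c] * a[c]
  }
  pmax(out, 0)
}

oracle_daeb <- function(x, p) {
  t <- oracle_conv3d(x, p$conv$W, p$conv$b)
  d <- dim(t)
  ca <- oracle_gap(t)
  ca <- oracle_fc(ca, p$fc1$W, p$fc1$b)
  ca <- pmax(ca, 0)
  ca <- oracle_fc(ca, p$fc2$W, p$fc2$b)
  ca <- 1 / (1 + exp(-ca))
  t_ca <- t
  for (bb in 1:d[1]) for (c in 1:d[5])
    t_ca[bb, , , , c] <- t[bb, , , , c] * ca[bb, 1, 1, 1, c]
  pooled <- array(0, c(d[1:4], 2))
  for (bb in 1:d[1]) for (i in 1:d[2]) for (j in 1:d[3]) for (k in 1:d[4]) {
    pooled[bb, i, j, k, 1] <- max(t[bb, i, j, k, ])
    pooled[bb, i, j, k, 2] <- mean(t[bb, i, j, k, ])
  }
  sa <- oracle_conv3d(pooled, p$sconv$W, p$sconv$b)
  sa <- 1 / (1 + exp(-sa))
  t_sa <- t
  for (c in 1:d[5]) t_sa[, , , , c] <- t[, , , , c] * sa[, , , , 1]
  t_ca + t_sa
}

oracle_segpath <- function(x, p, n) {
  if (n == 0) return(x)
  z <- NULL
  for (i in seq_len(n)) {
    it <- p[[sprintf("it%d", i)]]
    y1 <- pmax(oracle_bn(oracle_conv3d(x, it$c1$W, it$c1$b), it$bn1$gamma, it$bn1$beta), 0)
    y2 <- pmax(oracle_bn(oracle_conv3d(x, it$c3$W, it$c3$b), it$bn3$gamma, it$bn3$beta), 0)
    yi <- y1 + y2
    z <- if (is.null(z)) yi else z + yi
  }
  z
}

# Average Hausdorff distance by explicit double loop over coordinate rows.
oracle_ahd <- function(P, L, spacing = c(1, 1, 1)) {
  mind <- function(A, B) {
    out <- numeric(nrow(A))
    for (i in seq_len(nrow(A))) {
      best <- Inf
      for (j in seq_len(nrow(B))) {
        d <- sqrt(sum(((A[i, ] - B[j, ]) * spacing)^2))
        if (d < best) best <- d
      }
      out[i] <- best
    }
    out
  }
  0.5 * (mean(mind(P, L)) + mean(mind(L, P)))
}

random_tiny_tensor <- function(max_spatial = 3, max_channels = 4, batch = 1) {
  d <- c(batch, sample(1:max_spatial, 3, replace = TRUE),
         sample(1:max_channels, 1))
  array(rnorm(prod(d)), d)
}
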