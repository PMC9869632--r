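# Internal matrix implementation of the compact reference network.
# The stem reduces a patch to a 32 x 32 grid of block statistics: the
# block mean and block standard deviation of each RGB channel (6 input
# channels). Means carry stain color; SDs carry local texture energy
# (nucleus contrast, fiber striping, blur), which block means alone
# erase at coarse pooling factors.
#   input 32 x 32 x 6 (block mean + block SD per RGB channel)
#   conv 3x3x6 -> 8, valid, ReLU        -> 30 x 30 x 8
#   max pool 2x2                        -> 15 x 15 x 8
#   conv 3x3x8 -> 16, valid, ReLU       -> 13 x 13 x 16
#   max pool 2x2 (floor)                ->  6 x  6 x 16
#   global average pool                 -> 16
#   dense 16 -> 6, softmax
# Convolutions are im2col + BLAS matrix products; valid padding keeps
# per-patch outputs translation-consistent. ~1.5k parameters.

NET_IN <- 32L
NET_CH <- 6L

# linear-index im2col map for a (h, w, ch) array and k x k kernels:
# (k*k*ch) x (ho*wo) matrix of 1-based indices; window positions are
# column-major over the (ho, wo) output grid
im2col_idx <- function(h, w, ch, k = 3L) {
  ho <- h - k + 1L
  wo <- w - k + 1L
  dr <- rep(0:(k - 1L), times = k * ch)
  dc <- rep(rep(0:(k - 1L), each = k), times = ch)
  cc <- rep(0:(ch - 1L), each = k * k)
  off <- dr + dc * h + cc * h * w
  pos <- rep(0:(ho - 1L), times = wo) + rep(0:(wo - 1L), each = ho) * h
  outer(as.integer(off), as.integer(pos), "+") + 1L
}

net_geometry <- function() {
  list(idx1 = im2col_idx(32L, 32L, NET_CH), d1 = c(30L, 30L, 8L),
       idx2 = im2col_idx(15L, 15L, 8L), d2 = c(13L, 13L, 16L),
       in_len = 32L * 32L * NET_CH, mid_len = 15L * 15L * 8L)
}

net_init <- function(seed, n_classes = 6L) {
  local_seed(seed, {
    he <- function(nout, nin) {
      matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
    }
    list(W1 = he(8L, 9L * NET_CH), b1 = numeric(8L),
         W2 = he(16L, 72L), b2 = numeric(16L),
         Wd = he(6L, 16L), bd = numeric(6L))
  })
}

gather_cols <- function(z, idx, n, len) {
  big <- rep(as.integer(idx), n) +
    rep.int((0:(n - 1L)) * len, rep.int(length(idx), n))
  matrix(z[big], nrow(idx), ncol(idx) * n)
}

maxpool2 <- function(a) {
  d <- dim(a)
  ho <- d[1] %/% 2L
  wo <- d[2] %/% 2L
  r1 <- seq_len(ho) * 2L - 1L
  c1 <- seq_len(wo) * 2L - 1L
  s <- list(a[r1, c1, , , drop = FALSE], a[r1 + 1L, c1, , , drop = FALSE],
            a[r1, c1 + 1L, , , drop = FALSE],
            a[r1 + 1L, c1 + 1L, , , drop = FALSE])
  best <- s[[1]]
  arg <- array(1L, dim(best))
  for (j in 2:4) {
    upd <- s[[j]] > best
    arg[upd] <- j
    best[upd] <- s[[j]][upd]
  }
  list(out = best, arg = arg)
}

unpool2 <- function(g, arg, h, w) {
  d <- dim(g)
  dx <- array(0, c(h, w, d[3], d[4]))
  r1 <- seq_len(d[1]) * 2L - 1L
  c1 <- seq_len(d[2]) * 2L - 1L
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (j in 1:4) {
    tmp <- array(0, d)
    mask <- arg == j
    tmp[mask] <- g[mask]
    dx[r1 + offs[[j]][1], c1 + offs[[j]][2], , ] <- tmp
  }
  dx
}

# stem: block statistics of an (s, s, 3) patch at factor f = s / 32,
# flattened to a 32*32*6 vector (means then SDs, intensity units)
stem_features <- function(patch, f) {
  m <- pool_block(patch, f)
  if (f == 1) {
    v <- m * 0
  } else {
    v <- pmax(pool_block(patch^2, f) - m^2, 0)
  }
  c(as.vector(m), as.vector(sqrt(v)))
}

# forward pass on a 6144 x n matrix of stem features (0..255 scale);
# returns 6 x n class probabilities, plus intermediates when cache=TRUE
net_forward <- function(net, X, geom = net_geometry(), cache = FALSE) {
  n <- ncol(X)
  z <- X / 255
  z[seq_len(3072L), ] <- z[seq_len(3072L), ] - 0.5
  cols1 <- gather_cols(z, geom$idx1, n, geom$in_len)
  a1 <- net$W1 %*% cols1 + net$b1
  m1 <- a1 > 0
  a1[!m1] <- 0
  a1s <- aperm(array(a1, c(8L, 30L, 30L, n)), c(2, 3, 1, 4))
  p1 <- maxpool2(a1s)
  cols2 <- gather_cols(as.vector(p1$out), geom$idx2, n, geom$mid_len)
  a2 <- net$W2 %*% cols2 + net$b2
  m2 <- a2 > 0
  a2[!m2] <- 0
  a2s <- aperm(array(a2, c(16L, 13L, 13L, n)), c(2, 3, 1, 4))
  p2 <- maxpool2(a2s)
  G <- matrix(colMeans(matrix(p2$out, 36L)), 16L, n)
  logits <- net$Wd %*% G + net$bd
  logits <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(logits)
  probs <- sweep(e, 2, colSums(e), "/")
  if (!cache) return(probs)
  list(probs = probs, G = G, cols1 = cols1, cols2 = cols2,
       m1 = m1, m2 = m2, arg1 = p1$arg, arg2 = p2$arg, n = n)
}

col2im_grad <- function(dcols, idx, n, len) {
  big <- rep(as.integer(idx), n) +
    rep.int((0:(n - 1L)) * len, rep.int(length(idx), n))
  s <- rowsum(as.vector(dcols), group = big)
  dx <- numeric(len * n)
  dx[as.integer(rownames(s))] <- s
  dx
}

# cross-entropy gradient for one batch; y is 1-based class index
net_backward <- function(net, fw, y, geom = net_geometry()) {
  n <- fw$n
  dlog <- fw$probs
  dlog[cbind(y, seq_len(n))] <- dlog[cbind(y, seq_len(n))] - 1
  dlog <- dlog / n
  dWd <- dlog %*% t(fw$G)
  dbd <- rowSums(dlog)
  dG <- t(net$Wd) %*% dlog
  dp2 <- array(matrix(rep(as.vector(dG) / 36, each = 36L), 36L),
               c(6L, 6L, 16L, n))
  d2 <- unpool2(dp2, fw$arg2, 13L, 13L)
  dA2 <- matrix(aperm(d2, c(3, 1, 2, 4)), 16L)
  dA2[!fw$m2] <- 0
  dW2 <- dA2 %*% t(fw$cols2)
  db2 <- rowSums(dA2)
  dcols2 <- t(net$W2) %*% dA2
  dp1v <- col2im_grad(dcols2, geom$idx2, n, geom$mid_len)
  dp1 <- array(dp1v, c(15L, 15L, 8L, n))
  d1 <- unpool2(dp1, fw$arg1, 30L, 30L)
  dA1 <- matrix(aperm(d1, c(3, 1, 2, 4)), 8L)
  dA1[!fw$m1] <- 0
  dW1 <- dA1 %*% t(fw$cols1)
  db1 <- rowSums(dA1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, Wd = dWd, bd = dbd)
}

# Fully-convolutional dense forward: evaluates the network once over a
# whole pooled slide and reads each patch's prediction out of the
# shared feature maps. Valid convolutions are translation-consistent,
# max-pool partitions align because patch offsets on the pooled grid
# are even, and the second pool's two possible phases are both
# computed; the global average pool becomes a 6x6 box sum via integral
# images. Results match the per-patch forward pass to floating-point
# noise.
# pooled: (hp, wp, 6) stem features; y0p, x0p: even 0-based offsets of
# each patch window. Returns 6 x npts probabilities.
fast_dense_forward <- function(net, pooled, y0p, x0p) {
  hp <- dim(pooled)[1]
  wp <- dim(pooled)[2]
  z <- pooled / 255
  z[, , 1:3] <- z[, , 1:3] - 0.5
  conv <- function(x, W, b) {
    d <- dim(x)
    idx <- im2col_idx(d[1], d[2], d[3])
    a <- W %*% matrix(x[idx], nrow(idx)) + b
    a[a < 0] <- 0
    aperm(array(a, c(nrow(W), d[1] - 2L, d[2] - 2L)), c(2, 3, 1))
  }
  mpool <- function(x, pr, pc) {
    d <- dim(x)
    nt <- (d[1] - pr) %/% 2L
    ns <- (d[2] - pc) %/% 2L
    r1 <- pr + seq_len(nt) * 2L - 1L
    c1 <- pc + seq_len(ns) * 2L - 1L
    pmax(x[r1, c1, , drop = FALSE], x[r1 + 1L, c1, , drop = FALSE],
         x[r1, c1 + 1L, , drop = FALSE],
         x[r1 + 1L, c1 + 1L, , drop = FALSE])
  }
  a1 <- conv(z, net$W1, net$b1)
  p1 <- mpool(a1, 0L, 0L)
  a2 <- conv(p1, net$W2, net$b2)
  npts <- length(y0p)
  G <- matrix(0, 16L, npts)
  qy <- y0p %/% 2L
  qx <- x0p %/% 2L
  for (pr in 0:1) {
    for (pc in 0:1) {
      sel <- which(qy %% 2L == pr & qx %% 2L == pc)
      if (length(sel) == 0) next
      p2 <- mpool(a2, pr, pc)
      d <- dim(p2)
      cs <- apply(p2, c(2, 3), cumsum)                  # cumsum rows
      cs <- aperm(apply(cs, c(1, 3), cumsum), c(2, 1, 3))  # then cols
      S <- array(0, c(d[1] + 1L, d[2] + 1L, 16L))
      S[-1, -1, ] <- cs
      t0 <- (qy[sel] - pr) %/% 2L
      s0 <- (qx[sel] - pc) %/% 2L
      nS <- (d[1] + 1L) * (d[2] + 1L)
      choff <- (seq_len(16L) - 1L) * nS
      cell <- function(dt, ds) {
        base <- (t0 + dt) + (s0 + ds - 1L) * (d[1] + 1L)
        matrix(S[outer(base, choff, "+")], length(sel), 16L)
      }
      box <- cell(7L, 7L) - cell(1L, 7L) - cell(7L, 1L) + cell(1L, 1L)
      G[, sel] <- t(box) / 36
    }
  }
  logits <- net$Wd %*% G + net$bd
  logits <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(logits)
  sweep(e, 2, colSums(e), "/")
}
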