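# Low-level differentiable tensor primitives.
#
# All activations are dense double arrays with layout (nx, ny, nz, N, C):
# three spatial axes (nz = 1 for 2D feature maps), batch, then channels
# last. With channels slowest-varying, a flat matrix view of shape
# (nx*ny*nz*N, C) is a dim() change, not a copy, which keeps the GEMM-based
# convolution below allocation-light. Every *_fwd returns the output plus
# the cache its *_bwd needs; backward passes return exact gradients
# (validated against finite differences in the test suite).

#' @noRd
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# 0-based kernel offset table, row k -> (dx, dy, dz)
offset_table <- function(ksz) {
  as.matrix(expand.grid(dx = seq_len(ksz[1]) - 1L,
                        dy = seq_len(ksz[2]) - 1L,
                        dz = seq_len(ksz[3]) - 1L))
}

pad_spatial <- function(x, p) {
  if (all(p == 0L)) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p[1], d[2] + 2 * p[2], d[3] + 2 * p[3], d[4], d[5]))
  out[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]), p[3] + seq_len(d[3]), , ] <- x
  out
}

unpad_spatial <- function(xp, p, d) {
  if (all(p == 0L)) return(xp)
  xp[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]), p[3] + seq_len(d[3]), , , drop = FALSE]
}

# He-normal initialised convolution weights. W is (K, Cin, Cout) with K the
# flattened kernel positions; b length Cout.
conv_init <- function(ksz, cin, cout) {
  K <- prod(ksz)
  sd <- sqrt(2 / (K * cin))
  list(W = array(stats::rnorm(K * cin * cout, sd = sd), c(K, cin, cout)),
       b = numeric(cout))
}

# "Same"-padded convolution for odd kernels (kz = 1 gives a 2D conv on the
# degenerate z axis), computed as a sum of K shifted GEMMs. The production
# path is compiled (conv.cpp); conv_fwd_ref/conv_bwd_ref below are the
# plain-R reference used to cross-check it in the tests.
conv_fwd <- function(x, W, b, ksz) {
  out <- conv_fwd_cpp(x, dim(x), W, as.integer(ksz), b)
  list(out = out, x = x, din = dim(x))
}

conv_bwd <- function(cache, dy, W, ksz) {
  conv_bwd_cpp(cache$x, cache$din, dy, W, as.integer(ksz))
}

conv_fwd_ref <- function(x, W, b, ksz) {
  d <- dim(x)
  p <- (ksz - 1L) %/% 2L
  xp <- pad_spatial(x, p)
  n <- prod(d[1:4])
  ci <- d[5]
  co <- dim(W)[3]
  off <- offset_table(ksz)
  y <- matrix(rep(b, each = n), n, co)
  for (k in seq_len(nrow(off))) {
    xs <- xp[off[k, 1] + seq_len(d[1]), off[k, 2] + seq_len(d[2]),
             off[k, 3] + seq_len(d[3]), , , drop = FALSE]
    dim(xs) <- c(n, ci)
    y <- y + xs %*% matrix(W[k, , ], ci, co)
  }
  dim(y) <- c(d[1:4], co)
  list(out = y, xp = xp, din = d)
}

conv_bwd_ref <- function(cache, dy, W, ksz) {
  d <- cache$din
  p <- (ksz - 1L) %/% 2L
  xp <- cache$xp
  n <- prod(d[1:4])
  ci <- d[5]
  co <- dim(W)[3]
  off <- offset_table(ksz)
  dym <- dy
  dim(dym) <- c(n, co)
  dW <- array(0, dim(W))
  db <- colSums(dym)
  dxp <- array(0, dim(xp))
  for (k in seq_len(nrow(off))) {
    ix <- off[k, 1] + seq_len(d[1])
    iy <- off[k, 2] + seq_len(d[2])
    iz <- off[k, 3] + seq_len(d[3])
    xs <- xp[ix, iy, iz, , , drop = FALSE]
    dim(xs) <- c(n, ci)
    dW[k, , ] <- crossprod(xs, dym)
    dxs <- dym %*% t(matrix(W[k, , ], ci, co))
    dim(dxs) <- c(d[1:4], ci)
    dxp[ix, iy, iz, , ] <- dxp[ix, iy, iz, , , drop = FALSE] + dxs
  }
  list(dx = unpad_spatial(dxp, p, d), dW = dW, db = db)
}

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, mask = mask)
}

relu_bwd <- function(cache, dy) {
  dy[!cache$mask] <- 0
  dy
}

# Sum adjacent index pairs along one spatial axis (axis in 1:3).
pair_sum_axis <- function(x, axis) {
  d <- dim(x)
  i1 <- seq(1L, d[axis], by = 2L)
  i2 <- i1 + 1L
  switch(axis,
         x[i1, , , , , drop = FALSE] + x[i2, , , , , drop = FALSE],
         x[, i1, , , , drop = FALSE] + x[, i2, , , , drop = FALSE],
         x[, , i1, , , drop = FALSE] + x[, , i2, , , drop = FALSE])
}

# Duplicate every index along one spatial axis.
rep_axis <- function(x, axis) {
  d <- dim(x)
  i <- rep(seq_len(d[axis]), each = 2L)
  switch(axis,
         x[i, , , , , drop = FALSE],
         x[, i, , , , drop = FALSE],
         x[, , i, , , drop = FALSE])
}

# 2x mean pooling over the given spatial axes (each must be even).
pool_fwd <- function(x, axes) {
  for (a in axes) x <- pair_sum_axis(x, a)
  x / (2^length(axes))
}

pool_bwd <- function(dy, axes) {
  for (a in rev(axes)) dy <- rep_axis(dy, a)
  dy / (2^length(axes))
}

# 2x nearest-neighbour upsampling over the given spatial axes.
upsample_fwd <- function(x, axes) {
  for (a in rev(axes)) x <- rep_axis(x, a)
  x
}

upsample_bwd <- function(dy, axes) {
  for (a in axes) dy <- pair_sum_axis(dy, a)
  dy
}

cat_channels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1:4], da[5] + db[5]))
  out[, , , , seq_len(da[5])] <- a
  out[, , , , da[5] + seq_len(db[5])] <- b
  out
}

split_channels <- function(d, ca) {
  dd <- dim(d)
  list(a = d[, , , , seq_len(ca), drop = FALSE],
       b = d[, , , , ca + seq(dd[5] - ca), drop = FALSE])
}

# Softmax over the channel (last) axis; numerically stabilised.
softmax_channels <- function(z) {
  d <- dim(z)
  n <- prod(d[-length(d)])
  C <- d[length(d)]
  zm <- z
  dim(zm) <- c(n, C)
  mx <- do.call(pmax, lapply(seq_len(C), function(j) zm[, j]))
  e <- exp(zm - mx)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

# Given dL/dp for probabilities p = softmax(z), return dL/dz.
softmax_bwd <- function(p, dp) {
  d <- dim(p)
  n <- prod(d[-length(d)])
  C <- d[length(d)]
  pm <- p; dim(pm) <- c(n, C)
  dpm <- dp; dim(dpm) <- c(n, C)
  s <- rowSums(pm * dpm)
  dz <- pm * (dpm - s)
  dim(dz) <- d
  dz
}

# Row-wise layer norm over channels of a (T, C) token matrix.
ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc * xc) + eps)
  xn <- xc / sd
  Tn <- nrow(x)
  list(out = xn * rep(g, each = Tn) + rep(b, each = Tn), xn = xn, sd = sd)
}

ln_bwd <- function(cache, dy, g) {
  Tn <- nrow(dy)
  xn <- cache$xn
  dg <- colSums(dy * xn)
  db <- colSums(dy)
  dxn <- dy * rep(g, each = Tn)
  dx <- (dxn - rowMeans(dxn) - xn * rowMeans(dxn * xn)) / cache$sd
  list(dx = dx, dg = dg, db = db)
}
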