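# Network definitions.
#
# Two scale-configurable U-shaped encoder-decoders, written directly on the
# primitives in nn-ops.R with hand-derived backward passes:
#
#   * net2d: a 2D slice network with windowed self-attention blocks at the
#     two downsampled stages (tokens are non-overlapping window x window
#     tiles; pre-LayerNorm single-head attention with a residual
#     connection), convolutions for local mixing, and skip connections.
#   * net3d: a plain 3D convolutional U-Net with `n_levels` resolution
#     levels, two 3x3x3 convolutions per level and 2x mean-pool /
#     nearest-upsample transitions.
#
# Both emit per-voxel class logits; probabilities are softmax over the
# channel axis. In evaluation both are pure functions of (weights, input).

K331 <- c(3L, 3L, 1L)
K333 <- c(3L, 3L, 3L)
K111 <- c(1L, 1L, 1L)

#' Configuration for the 2D slice network
#'
#' A U-shaped 2D network operating on axial slices: a convolutional stem at
#' full resolution, two encoder stages at 1/2 and 1/4 resolution each
#' preceded by a windowed self-attention block, and a symmetric decoder with
#' skip connections. `embed_dim` sets the stem width; stage widths are
#' `embed_dim` and `2 * embed_dim`.
#'
#' @param in_channels Number of input channels (1 for grayscale slices).
#' @param n_classes Number of output classes (>= 2; 2 for binary masks).
#' @param embed_dim Stem channel width.
#' @param window Attention window edge length, in feature-map pixels; both
#'   downsampled stage sizes must be divisible by it.
#' @param input_size Integer vector `c(h, w)` the network is built for.
#' @return A `net2d_config` list.
#' @export
net2d_config <- function(in_channels = 1L, n_classes = 2L, embed_dim = 24L,
                         window = 4L, input_size = c(32L, 32L)) {
  stopifnot(n_classes >= 2L, embed_dim >= 2L, window >= 1L,
            length(input_size) == 2L, in_channels >= 1L)
  if (any(input_size %% (4L * window) != 0L)) {
    stop("input_size must be divisible by 4*window (two downsamplings, then windowing)")
  }
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 embed_dim = as.integer(embed_dim),
                 window = as.integer(window),
                 input_size = as.integer(input_size)),
            class = "net2d_config")
}

#' Configuration for the 3D patch network
#'
#' A 3D convolutional U-Net with `n_levels` resolution levels (so
#' `n_levels - 1` poolings); channel width doubles per level starting from
#' `base_channels`.
#'
#' @param in_channels Number of input channels.
#' @param n_classes Number of output classes (>= 2).
#' @param base_channels Channel width at full resolution.
#' @param n_levels Number of resolution levels.
#' @param input_size Integer vector `c(wx, wy, wz)`; every component must be
#'   divisible by `2^(n_levels - 1)`.
#' @return A `net3d_config` list.
#' @export
net3d_config <- function(in_channels = 1L, n_classes = 2L, base_channels = 8L,
                         n_levels = 3L, input_size = c(32L, 32L, 8L)) {
  stopifnot(n_classes >= 2L, base_channels >= 1L, n_levels >= 2L,
            length(input_size) == 3L, in_channels >= 1L)
  if (any(input_size %% (2L^(n_levels - 1L)) != 0L)) {
    stop("each input_size component must be divisible by 2^(n_levels-1)")
  }
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 base_channels = as.integer(base_channels),
                 n_levels = as.integer(n_levels),
                 input_size = as.integer(input_size)),
            class = "net3d_config")
}

attn_init <- function(C) {
  sd <- 1 / sqrt(C)
  list(g = rep(1, C), bln = rep(0, C),
       Wq = matrix(stats::rnorm(C * C, sd = sd), C, C),
       Wk = matrix(stats::rnorm(C * C, sd = sd), C, C),
       Wv = matrix(stats::rnorm(C * C, sd = sd), C, C),
       Wo = matrix(stats::rnorm(C * C, sd = 0.02), C, C))
}

# Partition (nx, ny, 1, N, C) into per-window token matrices (T, C, B).
win_partition <- function(x, w) {
  d <- dim(x)
  nx <- d[1]; ny <- d[2]; N <- d[4]; C <- d[5]
  nwx <- nx %/% w; nwy <- ny %/% w
  dim(x) <- c(w, nwx, w, nwy, N, C)
  x <- aperm(x, c(1, 3, 6, 2, 4, 5))
  dim(x) <- c(w * w, C, nwx * nwy * N)
  list(tok = x, meta = list(w = w, nwx = nwx, nwy = nwy, N = N, C = C))
}

win_unpartition <- function(tok, meta) {
  w <- meta$w
  dim(tok) <- c(w, w, meta$C, meta$nwx, meta$nwy, meta$N)
  tok <- aperm(tok, c(1, 4, 2, 5, 6, 3))  # inverse of c(1,3,6,2,4,5)
  dim(tok) <- c(w * meta$nwx, w * meta$nwy, 1L, meta$N, meta$C)
  tok
}

row_softmax <- function(S) {
  e <- exp(S - apply(S, 1, max))
  e / rowSums(e)
}

attn_fwd <- function(x, pars, w) {
  pt <- win_partition(x, w)
  tok <- pt$tok
  C <- pt$meta$C
  B <- dim(tok)[3]
  out <- tok
  caches <- vector("list", B)
  scl <- 1 / sqrt(C)
  for (b in seq_len(B)) {
    X <- tok[, , b]
    lnc <- ln_fwd(X, pars$g, pars$bln)
    Y <- lnc$out
    Q <- Y %*% pars$Wq
    K <- Y %*% pars$Wk
    V <- Y %*% pars$Wv
    A <- row_softmax(Q %*% t(K) * scl)
    O <- A %*% V
    out[, , b] <- X + O %*% pars$Wo
    caches[[b]] <- list(lnc = lnc, Y = Y, Q = Q, K = K, V = V, A = A, O = O)
  }
  list(out = win_unpartition(out, pt$meta), caches = caches, meta = pt$meta)
}

attn_bwd <- function(cache, dy, pars) {
  meta <- cache$meta
  pt <- win_partition(dy, meta$w)
  dtok <- pt$tok
  C <- meta$C
  B <- dim(dtok)[3]
  scl <- 1 / sqrt(C)
  dpars <- list(g = 0 * pars$g, bln = 0 * pars$bln, Wq = 0 * pars$Wq,
                Wk = 0 * pars$Wk, Wv = 0 * pars$Wv, Wo = 0 * pars$Wo)
  dx <- dtok
  for (b in seq_len(B)) {
    cb <- cache$caches[[b]]
    dOut <- dtok[, , b]
    dpars$Wo <- dpars$Wo + crossprod(cb$O, dOut)
    dO <- dOut %*% t(pars$Wo)
    dA <- dO %*% t(cb$V)
    dV <- crossprod(cb$A, dO)
    dS <- cb$A * (dA - rowSums(cb$A * dA))
    dQ <- dS %*% cb$K * scl
    dK <- crossprod(dS, cb$Q) * scl
    dY <- dQ %*% t(pars$Wq) + dK %*% t(pars$Wk) + dV %*% t(pars$Wv)
    dpars$Wq <- dpars$Wq + crossprod(cb$Y, dQ)
    dpars$Wk <- dpars$Wk + crossprod(cb$Y, dK)
    dpars$Wv <- dpars$Wv + crossprod(cb$Y, dV)
    lb <- ln_bwd(cb$lnc, dY, pars$g)
    dpars$g <- dpars$g + lb$dg
    dpars$bln <- dpars$bln + lb$db
    dx[, , b] <- dx[, , b] + lb$dx  # residual: dX = dOut + d(LN branch)
  }
  list(dx = win_unpartition(dx, meta), dpars = dpars)
}

#' Initialise the 2D slice network
#'
#' He-normal convolution weights and unit-gain LayerNorm; deterministic
#' given `seed`.
#'
#' @param config A [net2d_config()].
#' @param seed Integer RNG seed for the weight draw.
#' @return A model object of class `mdcseg_net2d`.
#' @export
net2d_init <- function(config, seed = 1L) {
  E <- config$embed_dim
  pars <- local_seed(seed, list(
    stem = conv_init(K331, config$in_channels, E),
    att1 = attn_init(E),
    enc1 = conv_init(K331, E, 2L * E),
    att2 = attn_init(2L * E),
    enc2 = conv_init(K331, 2L * E, 2L * E),
    dec1c = conv_init(K111, 4L * E, E),   # 1x1 compression of the concat
    dec1 = conv_init(K331, E, E),
    dec0c = conv_init(K111, 2L * E, E),
    dec0 = conv_init(K331, E, E),
    head = conv_init(K111, E, config$n_classes)))
  structure(list(config = config, params = pars, seed = as.integer(seed)),
            class = "mdcseg_net2d")
}

net2d_fwd <- function(pars, x, cfg, with_cache = TRUE) {
  w <- cfg$window
  c1 <- conv_fwd(x, pars$stem$W, pars$stem$b, K331); r1 <- relu_fwd(c1$out)
  p1 <- pool_fwd(r1$out, 1:2)
  a1 <- attn_fwd(p1, pars$att1, w)
  c2 <- conv_fwd(a1$out, pars$enc1$W, pars$enc1$b, K331); r2 <- relu_fwd(c2$out)
  p2 <- pool_fwd(r2$out, 1:2)
  a2 <- attn_fwd(p2, pars$att2, w)
  c3 <- conv_fwd(a2$out, pars$enc2$W, pars$enc2$b, K331); r3 <- relu_fwd(c3$out)
  u1 <- upsample_fwd(r3$out, 1:2)
  k1 <- cat_channels(u1, r2$out)
  c4c <- conv_fwd(k1, pars$dec1c$W, pars$dec1c$b, K111); r4c <- relu_fwd(c4c$out)
  c4 <- conv_fwd(r4c$out, pars$dec1$W, pars$dec1$b, K331); r4 <- relu_fwd(c4$out)
  u0 <- upsample_fwd(r4$out, 1:2)
  k0 <- cat_channels(u0, r1$out)
  c5c <- conv_fwd(k0, pars$dec0c$W, pars$dec0c$b, K111); r5c <- relu_fwd(c5c$out)
  c5 <- conv_fwd(r5c$out, pars$dec0$W, pars$dec0$b, K331); r5 <- relu_fwd(c5$out)
  h <- conv_fwd(r5$out, pars$head$W, pars$head$b, K111)
  cache <- if (with_cache) list(c1 = c1, r1 = r1, a1 = a1, c2 = c2, r2 = r2,
                                a2 = a2, c3 = c3, r3 = r3, c4c = c4c, r4c = r4c,
                                c4 = c4, r4 = r4, c5c = c5c, r5c = r5c,
                                c5 = c5, r5 = r5, h = h) else NULL
  list(logits = h$out, cache = cache)
}

net2d_bwd <- function(pars, cache, dlogits, cfg) {
  E <- cfg$embed_dim
  g <- list()
  bh <- conv_bwd(cache$h, dlogits, pars$head$W, K111)
  g$head <- list(W = bh$dW, b = bh$db)
  d5 <- relu_bwd(cache$r5, bh$dx)
  b5 <- conv_bwd(cache$c5, d5, pars$dec0$W, K331)
  g$dec0 <- list(W = b5$dW, b = b5$db)
  d5c <- relu_bwd(cache$r5c, b5$dx)
  b5c <- conv_bwd(cache$c5c, d5c, pars$dec0c$W, K111)
  g$dec0c <- list(W = b5c$dW, b = b5c$db)
  sp0 <- split_channels(b5c$dx, E)
  d4 <- relu_bwd(cache$r4, upsample_bwd(sp0$a, 1:2))
  b4 <- conv_bwd(cache$c4, d4, pars$dec1$W, K331)
  g$dec1 <- list(W = b4$dW, b = b4$db)
  d4c <- relu_bwd(cache$r4c, b4$dx)
  b4c <- conv_bwd(cache$c4c, d4c, pars$dec1c$W, K111)
  g$dec1c <- list(W = b4c$dW, b = b4c$db)
  sp1 <- split_channels(b4c$dx, 2L * E)
  d3 <- relu_bwd(cache$r3, upsample_bwd(sp1$a, 1:2))
  b3 <- conv_bwd(cache$c3, d3, pars$enc2$W, K331)
  g$enc2 <- list(W = b3$dW, b = b3$db)
  ba2 <- attn_bwd(cache$a2, b3$dx, pars$att2)
  g$att2 <- ba2$dpars
  d2 <- relu_bwd(cache$r2, pool_bwd(ba2$dx, 1:2) + sp1$b)  # pooled path + skip
  b2 <- conv_bwd(cache$c2, d2, pars$enc1$W, K331)
  g$enc1 <- list(W = b2$dW, b = b2$db)
  ba1 <- attn_bwd(cache$a1, b2$dx, pars$att1)
  g$att1 <- ba1$dpars
  d1 <- relu_bwd(cache$r1, pool_bwd(ba1$dx, 1:2) + sp0$b)
  b1 <- conv_bwd(cache$c1, d1, pars$stem$W, K331)
  g$stem <- list(W = b1$dW, b = b1$db)
  g
}

#' Initialise the 3D patch network
#'
#' @param config A [net3d_config()].
#' @param seed Integer RNG seed for the weight draw.
#' @return A model object of class `mdcseg_net3d`.
#' @export
net3d_init <- function(config, seed = 1L) {
  L <- config$n_levels
  ch <- config$base_channels * 2L^(seq_len(L) - 1L)
  pars <- local_seed(seed, {
    enc <- vector("list", L)
    for (l in seq_len(L)) {
      cin <- if (l == 1L) config$in_channels else ch[l - 1L]
      enc[[l]] <- if (l < L) list(a = conv_init(K333, cin, ch[l]))
                  else list(a = conv_init(K333, cin, ch[l]),      # bottleneck
                            b = conv_init(K333, ch[l], ch[l]))    # gets depth 2
    }
    dec <- vector("list", L - 1L)
    for (l in seq_len(L - 1L)) {
      # 1x1x1 channel compression of the (upsampled + skip) concat, then 3x3x3
      dec[[l]] <- list(c = conv_init(K111, ch[l + 1L] + ch[l], ch[l]),
                       a = conv_init(K333, ch[l], ch[l]))
    }
    list(enc = enc, dec = dec, head = conv_init(K111, ch[1L], config$n_classes))
  })
  structure(list(config = config, params = pars, seed = as.integer(seed)),
            class = "mdcseg_net3d")
}

net3d_fwd <- function(pars, x, cfg, with_cache = TRUE) {
  L <- cfg$n_levels
  ec <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    if (l > 1L) h <- pool_fwd(h, 1:3)
    ca <- conv_fwd(h, pars$enc[[l]]$a$W, pars$enc[[l]]$a$b, K333)
    ra <- relu_fwd(ca$out)
    if (l == L) {
      cb <- conv_fwd(ra$out, pars$enc[[l]]$b$W, pars$enc[[l]]$b$b, K333)
      rb <- relu_fwd(cb$out)
      ec[[l]] <- list(ca = ca, ra = ra, cb = cb, rb = rb)
      h <- rb$out
    } else {
      ec[[l]] <- list(ca = ca, ra = ra)
      h <- ra$out
    }
  }
  dc <- vector("list", L - 1L)
  for (l in rev(seq_len(L - 1L))) {
    u <- upsample_fwd(h, 1:3)
    k <- cat_channels(u, ec[[l]]$ra$out)
    cc <- conv_fwd(k, pars$dec[[l]]$c$W, pars$dec[[l]]$c$b, K111)
    rc <- relu_fwd(cc$out)
    ca <- conv_fwd(rc$out, pars$dec[[l]]$a$W, pars$dec[[l]]$a$b, K333)
    ra <- relu_fwd(ca$out)
    dc[[l]] <- list(cc = cc, rc = rc, ca = ca, ra = ra)
    h <- ra$out
  }
  hd <- conv_fwd(h, pars$head$W, pars$head$b, K111)
  cache <- if (with_cache) list(ec = ec, dc = dc, hd = hd) else NULL
  list(logits = hd$out, cache = cache)
}

net3d_bwd <- function(pars, cache, dlogits, cfg) {
  L <- cfg$n_levels
  ch <- cfg$base_channels * 2L^(seq_len(L) - 1L)
  g <- list(enc = vector("list", L), dec = vector("list", L - 1L))
  bh <- conv_bwd(cache$hd, dlogits, pars$head$W, K111)
  g$head <- list(W = bh$dW, b = bh$db)
  dskip <- vector("list", L)  # gradient arriving at each encoder output via skips
  d <- bh$dx
  for (l in seq_len(L - 1L)) {
    dca <- relu_bwd(cache$dc[[l]]$ra, d)
    ba <- conv_bwd(cache$dc[[l]]$ca, dca, pars$dec[[l]]$a$W, K333)
    dcc <- relu_bwd(cache$dc[[l]]$rc, ba$dx)
    bc <- conv_bwd(cache$dc[[l]]$cc, dcc, pars$dec[[l]]$c$W, K111)
    g$dec[[l]] <- list(c = list(W = bc$dW, b = bc$db), a = list(W = ba$dW, b = ba$db))
    sp <- split_channels(bc$dx, ch[l + 1L])
    dskip[[l]] <- sp$b
    d <- upsample_bwd(sp$a, 1:3)  # toward the level above (l+1)
  }
  for (l in rev(seq_len(L))) {
    if (l < L) d <- d + dskip[[l]]
    if (l == L) {
      dcb <- relu_bwd(cache$ec[[l]]$rb, d)
      bb <- conv_bwd(cache$ec[[l]]$cb, dcb, pars$enc[[l]]$b$W, K333)
      dca <- relu_bwd(cache$ec[[l]]$ra, bb$dx)
      ba <- conv_bwd(cache$ec[[l]]$ca, dca, pars$enc[[l]]$a$W, K333)
      g$enc[[l]] <- list(a = list(W = ba$dW, b = ba$db),
                         b = list(W = bb$dW, b = bb$db))
    } else {
      dca <- relu_bwd(cache$ec[[l]]$ra, d)
      ba <- conv_bwd(cache$ec[[l]]$ca, dca, pars$enc[[l]]$a$W, K333)
      g$enc[[l]] <- list(a = list(W = ba$dW, b = ba$db))
    }
    d <- if (l > 1L) pool_bwd(ba$dx, 1:3) else ba$dx
  }
  g
}

# --- user-facing forward contracts ---------------------------------------

canon_2d_batch <- function(x, cfg) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (length(d) != 3L) stop("expected a (h, w) slice or (h, w, N) slice batch")
  if (!all(d[1:2] == cfg$input_size)) {
    stop(sprintf("slice size %dx%d does not match the model input size %dx%d",
                 d[1], d[2], cfg$input_size[1], cfg$input_size[2]))
  }
  dim(x) <- c(d[1], d[2], 1L, d[3], 1L)
  x
}

canon_3d_batch <- function(x, cfg) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  d <- dim(x)
  if (length(d) != 4L) stop("expected a (wx, wy, wz) patch or (wx, wy, wz, N) batch")
  if (!all(d[1:3] == cfg$input_size)) {
    stop(sprintf("patch size %s does not match the model input size %s",
                 paste(d[1:3], collapse = "x"),
                 paste(cfg$input_size, collapse = "x")))
  }
  dim(x) <- c(d[1], d[2], d[3], d[4], 1L)
  x
}

#' Forward pass of the 2D slice network
#'
#' Returns per-pixel class probabilities (softmax over the class axis; each
#' pixel's vector sums to 1). A pure function of (weights, input).
#'
#' @param model An `mdcseg_net2d` object.
#' @param x A `(h, w)` matrix or `(h, w, N)` array of slices.
#' @return Probabilities as `(h, w, n_classes)` for a single slice or
#'   `(h, w, N, n_classes)` for a batch; the class axis is last.
#' @export
forward_2d <- function(model, x) {
  single <- is.matrix(x)
  xb <- canon_2d_batch(x, model$config)
  p <- softmax_channels(net2d_fwd(model$params, xb, model$config, with_cache = FALSE)$logits)
  d <- dim(p)
  dim(p) <- c(d[1], d[2], d[4], d[5])
  if (single) { dp <- dim(p); dim(p) <- dp[-3] }
  p
}

#' Forward pass of the 3D patch network
#'
#' @param model An `mdcseg_net3d` object.
#' @param x A `(wx, wy, wz)` array or `(wx, wy, wz, N)` batch.
#' @return Probabilities `(wx, wy, wz, n_classes)` or
#'   `(wx, wy, wz, N, n_classes)`; the class axis is last.
#' @export
forward_3d <- function(model, x) {
  single <- length(dim(x)) == 3L
  xb <- canon_3d_batch(x, model$config)
  p <- softmax_channels(net3d_fwd(model$params, xb, model$config, with_cache = FALSE)$logits)
  if (single) { dp <- dim(p); dim(p) <- dp[-4] }
  p
}

#' Count trainable parameters of a model
#' @param model An `mdcseg_net2d` or `mdcseg_net3d` object.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  as.integer(cnt(model$params))
}

#' @export
print.mdcseg_net2d <- function(x, ...) {
  cat(sprintf("<mdcseg_net2d> embed_dim=%d window=%d input=%s params=%d\n",
              x$config$embed_dim, x$config$window,
              paste(x$config$input_size, collapse = "x"), n_params(x)))
  invisible(x)
}

#' @export
print.mdcseg_net3d <- function(x, ...) {
  cat(sprintf("<mdcseg_net3d> base=%d levels=%d input=%s params=%d\n",
              x$config$base_channels, x$config$n_levels,
              paste(x$config$input_size, collapse = "x"), n_params(x)))
  invisible(x)
}
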