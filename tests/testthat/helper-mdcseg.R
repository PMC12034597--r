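# Shared fixtures and independent oracles, all built in code at test time.

tiny_net2d_config <- function() {
  net2d_config(embed_dim = 4L, window = 2L, input_size = c(8L, 8L))
}

tiny_net3d_config <- function() {
  net3d_config(base_channels = 2L, n_levels = 2L, input_size = c(8L, 8L, 4L))
}

micro_spec <- function(n_tubes = 1L, n_confounders = 1L, ...) {
  phantom_spec(grid_size = c(32L, 32L, 16L), tube_radius_range = c(2.5, 4),
               n_tubes = n_tubes, n_confounders = n_confounders, ...)
}

# Plain-loop scalar reference implementation of the loss algebra, kept
# deliberately independent of the package's vectorized code paths.
ref_losses <- function(pred, target, alpha = 0.3, s = 1e-5) {
  d <- dim(pred)
  C <- d[length(d)]
  n <- prod(d[-length(d)])
  pm <- matrix(pred, n, C)
  tv <- as.integer(target)
  ce <- 0
  for (i in seq_len(n)) ce <- ce - log(max(pm[i, tv[i] + 1], 1e-12))
  ce <- ce / n
  num <- s
  den <- s
  sp <- 0; st <- 0; spt <- 0
  for (i in seq_len(n)) {
    p1 <- pm[i, 2]
    t1 <- as.numeric(tv[i] == 1L)
    sp <- sp + p1; st <- st + t1; spt <- spt + p1 * t1
  }
  dice <- 1 - (2 * spt + s) / (sp + st + s)
  sup <- alpha * ce + (1 - alpha) * dice
  list(l_ce = ce, l_dice = dice, l_sup = sup)
}

# Random (n1, n2, n3) probability field with a trailing 2-class axis.
random_prob <- function(d) {
  p1 <- array(stats::runif(prod(d)), d)
  out <- array(0, c(d, 2L))
  out[, , , 1] <- 1 - p1
  out[, , , 2] <- p1
  out
}

# 6-connected component count by iterative region growing.
count_components6 <- function(lab) {
  remaining <- lab == 1L
  d <- dim(lab)
  grow <- function(comp) {
    g <- comp
    g[-1, , ] <- g[-1, , ] | comp[-d[1], , ]
    g[-d[1], , ] <- g[-d[1], , ] | comp[-1, , ]
    g[, -1, ] <- g[, -1, ] | comp[, -d[2], ]
    g[, -d[2], ] <- g[, -d[2], ] | comp[, -1, ]
    g[, , -1] <- g[, , -1] | comp[, , -d[3]]
    g[, , -d[3]] <- g[, , -d[3]] | comp[, , -1]
    g
  }
  n <- 0L
  while (any(remaining)) {
    n <- n + 1L
    seedv <- which(remaining, arr.ind = TRUE)[1, ]
    comp <- array(FALSE, d)
    comp[seedv[1], seedv[2], seedv[3]] <- TRUE
    repeat {
      nxt <- grow(comp) & remaining
      if (sum(nxt) == sum(comp)) break
      comp <- nxt
    }
    remaining <- remaining & !comp
  }
  n
}

# A 2D (slice, labels) crop with substantial foreground, for overfit tests.
fg_slice_crop <- function(size = 32L, seed = 11L) {
  ph <- make_phantom(phantom_spec(seed = seed), "overfit")
  z <- which.max(apply(ph$mask$labels, 3, sum))
  d <- dim(ph$mask$labels)
  best <- c(1L, 1L); bv <- -1
  for (ox in seq(1L, d[1] - size + 1L, by = 8L)) {
    for (oy in seq(1L, d[2] - size + 1L, by = 8L)) {
      v <- sum(ph$mask$labels[ox:(ox + size - 1L), oy:(oy + size - 1L), z])
      if (v > bv) { bv <- v; best <- c(ox, oy) }
    }
  }
  rx <- best[1]:(best[1] + size - 1L)
  ry <- best[2]:(best[2] + size - 1L)
  list(slice = ph$volume$intensities[rx, ry, z],
       labels = ph$mask$labels[rx, ry, z],
       volume = ph$volume, mask = ph$mask, rx = rx, ry = ry, z = z)
}

# Gradient-descent overfit of the 2D network on one slice.
overfit_2d <- function(n_steps = 60L, lr = 0.05, seed = 11L) {
  cr <- fg_slice_crop(32L, seed)
  model <- net2d_init(net2d_config(), seed = 1L)
  pars <- model$params
  vel <- mdcseg:::tree_zero(pars)
  w <- loss_weights()
  xb <- array(cr$slice, c(32, 32, 1, 1, 1))
  yb <- array(cr$labels, c(32, 32, 1, 1))
  losses <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    fw <- mdcseg:::net2d_fwd(pars, xb, model$config)
    lg <- mdcseg:::sup_loss_grad(fw$logits, yb, w)
    gr <- mdcseg:::net2d_bwd(pars, fw$cache, lg$dz, model$config)
    up <- mdcseg:::sgd_step(pars, gr, vel, lr, 0.9)
    pars <- up$pars
    vel <- up$vel
    losses[s] <- lg$l_sup
  }
  model$params <- pars
  pred <- argmax_labels(forward_2d(model, cr$slice))
  list(model = model, losses = losses, labels = cr$labels, pred = pred,
       dice = seg_metrics(as.integer(cr$labels), as.integer(pred))$dice,
       crop = cr)
}

overfit_3d <- function(n_steps = 130L, lr = 0.05, seed = 11L) {
  cr <- fg_slice_crop(32L, seed)
  d3 <- dim(cr$volume$intensities)[3]
  zr <- pmin(pmax((cr$z - 4L):(cr$z + 3L), 1L), d3)
  x <- cr$volume$intensities[cr$rx, cr$ry, zr]
  y <- cr$mask$labels[cr$rx, cr$ry, zr]
  model <- net3d_init(net3d_config(), seed = 1L)
  pars <- model$params
  vel <- mdcseg:::tree_zero(pars)
  w <- loss_weights()
  xb <- array(x, c(32, 32, 8, 1, 1))
  yb <- array(y, c(32, 32, 8, 1))
  losses <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    fw <- mdcseg:::net3d_fwd(pars, xb, model$config)
    lg <- mdcseg:::sup_loss_grad(fw$logits, yb, w)
    gr <- mdcseg:::net3d_bwd(pars, fw$cache, lg$dz, model$config)
    up <- mdcseg:::sgd_step(pars, gr, vel, lr, 0.9)
    pars <- up$pars
    vel <- up$vel
    losses[s] <- lg$l_sup
  }
  model$params <- pars
  pred <- argmax_labels(forward_3d(model, x))
  list(model = model, losses = losses, labels = y, pred = pred,
       dice = seg_metrics(as.integer(y), as.integer(pred))$dice,
       x = x)
}
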