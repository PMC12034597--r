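# Loss algebra for the two-step pipeline.
#
# The supervised loss is a weighted sum of cross-entropy and soft Dice,
#   L_sup = alpha * L_ce + (1 - alpha) * L_dice,     alpha = 0.3 by default;
# the unsupervised consistency loss on pseudo-labeled patches is soft Dice
# alone (Dice tolerates the severe foreground/background imbalance that
# makes CE on pseudo-labels unstable); the total is their unweighted sum,
#   L_total = L_sup + L_un.
#
# Soft Dice is computed on the foreground class only, per batch item, then
# averaged over the batch. Losses consume probabilities, never hard labels;
# argmax happens only at pseudo-label generation and inference time.

CE_FLOOR <- 1e-12

#' Loss weights for the compound supervised loss
#'
#' @param alpha Weight on the cross-entropy term, in \[0, 1\]; the Dice term
#'   gets `1 - alpha`. Default 0.3.
#' @param dice_smooth Additive smoothing constant in the soft-Dice ratio;
#'   keeps the loss defined (and 0) when both prediction and target are
#'   empty.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(alpha = 0.3, dice_smooth = 1e-5) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(dice_smooth), length(dice_smooth) == 1L, dice_smooth > 0)
  structure(list(alpha = alpha, dice_smooth = dice_smooth), class = "loss_weights")
}

check_pred_target <- function(pred, target) {
  dp <- dim(pred)
  if (is.null(dp) || length(dp) < 2L) stop("pred must be an array with a trailing class axis")
  C <- dp[length(dp)]
  dt <- if (is.null(dim(target))) length(target) else dim(target)
  if (!isTRUE(all.equal(prod(dp[-length(dp)]), prod(dt)))) {
    stop("target shape does not match pred's spatial shape")
  }
  if (any(target < 0 | target >= C)) stop("target values must lie in 0..(classes-1)")
  C
}

#' Cross-entropy loss
#'
#' Mean over elements of `-log p(target class)`, with probabilities floored
#' at 1e-12 before the log so that a (numerically) zero probability at a
#' target element yields a large finite loss rather than `Inf`.
#'
#' @param pred Probability array whose last axis is the class axis.
#' @param target Integer array of class indices in `0..(classes-1)` matching
#'   `pred`'s spatial shape.
#' @return Non-negative scalar.
#' @export
ce_loss <- function(pred, target) {
  C <- check_pred_target(pred, target)
  n <- prod(dim(pred)[-length(dim(pred))])
  pm <- pred
  dim(pm) <- c(n, C)
  idx <- cbind(seq_len(n), as.integer(target) + 1L)
  -mean(log(pmax(pm[idx], CE_FLOOR)))
}

#' Soft Dice loss on the foreground class
#'
#' `1 - (2 * sum(p1 * t1) + s) / (sum(p1) + sum(t1) + s)` where `p1` is the
#' predicted foreground probability, `t1` the binary foreground target and
#' `s = dice_smooth`. Lies in \[0, 1\]; an empty target with an empty
#' prediction gives exactly 0 (the smoothing makes the ratio `s/s`).
#'
#' @inheritParams ce_loss
#' @param dice_smooth Smoothing constant `s` (default 1e-5).
#' @return Scalar in \[0, 1\].
#' @export
dice_loss <- function(pred, target, dice_smooth = 1e-5) {
  C <- check_pred_target(pred, target)
  n <- prod(dim(pred)[-length(dim(pred))])
  pm <- pred
  dim(pm) <- c(n, C)
  p1 <- pm[, 2L]
  t1 <- as.numeric(as.integer(target) == 1L)
  1 - (2 * sum(p1 * t1) + dice_smooth) / (sum(p1) + sum(t1) + dice_smooth)
}

#' Compound supervised loss (weighted CE + Dice)
#'
#' @inheritParams ce_loss
#' @param w A [loss_weights()] object.
#' @return A `loss_report` list with `l_ce`, `l_dice` and
#'   `l_sup = alpha * l_ce + (1 - alpha) * l_dice`.
#' @export
supervised_loss <- function(pred, target, w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"))
  l_ce <- ce_loss(pred, target)
  l_dice <- dice_loss(pred, target, w$dice_smooth)
  structure(list(l_ce = l_ce, l_dice = l_dice,
                 l_sup = w$alpha * l_ce + (1 - w$alpha) * l_dice),
            class = "loss_report")
}

#' Unsupervised consistency loss against pseudo-labels
#'
#' Soft Dice of the 3D network's foreground probability against the frozen
#' pseudo-label; no cross-entropy term. Identical, value for value, to
#' [dice_loss()] — pseudo-labels are plain integer constants, so no
#' gradient can reach the network that produced them.
#'
#' @param pred_3d Probability array (class axis last).
#' @param pseudo Integer pseudo-label array in `{0, 1}`.
#' @param dice_smooth Smoothing constant.
#' @return Scalar in \[0, 1\].
#' @export
unsupervised_loss <- function(pred_3d, pseudo, dice_smooth = 1e-5) {
  if (any(pseudo != 0L & pseudo != 1L)) stop("pseudo-label values must be in {0, 1}")
  dice_loss(pred_3d, pseudo, dice_smooth)
}

#' Total training loss for the 3D network
#'
#' The unweighted sum of the supervised and unsupervised terms.
#'
#' @param sup A `loss_report` from [supervised_loss()] (or a scalar `l_sup`).
#' @param un Scalar unsupervised loss.
#' @return Scalar `l_sup + l_un`.
#' @export
total_loss <- function(sup, un) {
  l_sup <- if (inherits(sup, "loss_report")) sup$l_sup else sup
  stopifnot(is.numeric(l_sup), is.numeric(un))
  l_sup + un
}

# --- batched loss + gradient, training internals -------------------------

# Per-item soft Dice and its gradient wrt foreground probability.
# p: (nx,ny,nz,N,C) probabilities; t: (nx,ny,nz,N) 0/1 targets.
# Returns mean loss over items and dL/dp (same shape as p, background-class
# gradient zero).
dice_grad_batch <- function(p, t, s) {
  d <- dim(p)
  N <- d[4]
  nvox <- prod(d[1:3])
  p1 <- p[, , , , 2L, drop = FALSE]
  dim(p1) <- c(nvox, N)
  tm <- as.numeric(t)
  dim(tm) <- c(nvox, N)
  Sp <- colSums(p1)
  St <- colSums(tm)
  Spt <- colSums(p1 * tm)
  den <- Sp + St + s
  num <- 2 * Spt + s
  loss <- mean(1 - num / den)
  # d/dp1 of (1 - num/den) = -(2*t*den - num)/den^2, averaged over items
  g1 <- -(2 * tm * rep(den, each = nvox) - rep(num, each = nvox)) /
    rep(den^2, each = nvox) / N
  dp <- array(0, d)
  dp[, , , , 2L] <- g1
  list(loss = loss, dp = dp)
}

# Supervised CE+Dice loss and gradient wrt logits for a batch.
# logits: (nx,ny,nz,N,C); target: (nx,ny,nz,N) integer 0/1.
sup_loss_grad <- function(logits, target, w) {
  p <- softmax_channels(logits)
  d <- dim(p)
  n <- prod(d[1:4])
  C <- d[5]
  pm <- p
  dim(pm) <- c(n, C)
  idx <- cbind(seq_len(n), as.integer(target) + 1L)
  pt <- pmax(pm[idx], CE_FLOOR)
  l_ce <- -mean(log(pt))
  dg <- dice_grad_batch(p, target, w$dice_smooth)
  # CE gradient through softmax is (p - onehot)/n; Dice gradient goes
  # through the softmax Jacobian explicitly.
  onehot <- matrix(0, n, C)
  onehot[idx] <- 1
  dz_ce <- (pm - onehot) / n
  dim(dz_ce) <- d
  dz <- w$alpha * dz_ce + (1 - w$alpha) * softmax_bwd(p, dg$dp)
  list(l_ce = l_ce, l_dice = dg$loss,
       l_sup = w$alpha * l_ce + (1 - w$alpha) * dg$loss, dz = dz)
}

# Dice-only loss and gradient wrt logits (unsupervised term).
un_loss_grad <- function(logits, pseudo, dice_smooth) {
  p <- softmax_channels(logits)
  dg <- dice_grad_batch(p, pseudo, dice_smooth)
  list(l_un = dg$loss, dz = softmax_bwd(p, dg$dp))
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("loss_report: l_ce=%.6f l_dice=%.6f l_sup=%.6f\n",
              x$l_ce, x$l_dice, x$l_sup))
  invisible(x)
}
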