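# Two-step training orchestration.
#
# Step 1 trains the 2D slice network on axial slices from the labeled
# volumes' patches with the compound supervised loss. Step 2 trains the 3D
# patch network: every optimization step draws a labeled batch (supervised
# CE+Dice loss) and an unlabeled batch scored against its frozen
# pseudo-labels (Dice-only consistency loss); the total loss is their
# unweighted sum. Both steps use SGD with momentum under a poly learning
# rate schedule, select the checkpoint with the best validation Dice, and
# stop early when validation Dice has not improved for `patience` epochs.

#' Training configuration
#'
#' @param max_epochs Epoch cap (>= 1).
#' @param patience Early-stopping patience in epochs (>= 1).
#' @param lr0 Initial learning rate (> 0).
#' @param poly_power Exponent of the poly schedule
#'   `lr = lr0 * (1 - epoch/max_epochs)^poly_power`.
#' @param momentum SGD momentum.
#' @param batch_size Items per optimization step (per branch in step 2).
#' @param steps_per_epoch Optimization steps per epoch; `NULL` means one
#'   full pass over the labeled patches.
#' @param window,stride Patch window and stride, `c(x, y, z)` voxels.
#' @param alpha CE weight in the supervised loss.
#' @param dice_smooth Soft-Dice smoothing constant.
#' @param augment_flip,augment_cutout Augmentation switches (cut-out
#'   applies to 3D patches only, and only to the image).
#' @param cutout_frac Target cut-out box volume as a fraction of the patch
#'   volume.
#' @param val_every Validate (and update early stopping) every this many
#'   epochs.
#' @param seed Training seed (batch order, augmentation draws).
#' @return An `mdcseg_train_config` list.
#' @export
train_config <- function(max_epochs = 500L, patience = 30L, lr0 = 0.01,
                         poly_power = 0.9, momentum = 0.9, batch_size = 8L,
                         steps_per_epoch = NULL,
                         window = c(256L, 256L, 16L), stride = c(128L, 128L, 8L),
                         alpha = 0.3, dice_smooth = 1e-5,
                         augment_flip = TRUE, augment_cutout = TRUE,
                         cutout_frac = 0.1, val_every = 1L, seed = 1L) {
  stopifnot(max_epochs >= 1L, patience >= 1L, lr0 > 0, poly_power >= 0,
            batch_size >= 1L, length(window) == 3L, length(stride) == 3L,
            val_every >= 1L, cutout_frac > 0, cutout_frac < 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr0 = lr0,
                 poly_power = poly_power, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 steps_per_epoch = steps_per_epoch,
                 window = as.integer(window), stride = as.integer(stride),
                 alpha = alpha, dice_smooth = dice_smooth,
                 augment_flip = isTRUE(augment_flip),
                 augment_cutout = isTRUE(augment_cutout),
                 cutout_frac = cutout_frac, val_every = as.integer(val_every),
                 seed = as.integer(seed)),
            class = "mdcseg_train_config")
}

#' Poly learning-rate schedule
#'
#' `lr = lr0 * (1 - epoch/max_epochs)^poly_power`: equals `lr0` at epoch 0,
#' decays strictly (for `poly_power > 0`) to 0 at `max_epochs`.
#'
#' @param epoch 0-based epoch index in `0..max_epochs`.
#' @param cfg An `mdcseg_train_config`.
#' @return Learning rate scalar.
#' @export
poly_lr <- function(epoch, cfg) {
  if (epoch < 0 || epoch > cfg$max_epochs) stop("epoch out of range 0..max_epochs")
  cfg$lr0 * (1 - epoch / cfg$max_epochs)^cfg$poly_power
}

flip_mat <- function(m, h, v) {
  if (h) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (v) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  m
}

#' Random flip augmentation for a slice and its labels
#'
#' Horizontal and vertical flips, each drawn with probability 1/2 and
#' applied identically to image and labels. Deterministic given `seed`.
#'
#' @param slice 2D numeric matrix.
#' @param labels 2D integer matrix (same shape).
#' @param seed Integer seed.
#' @return `list(slice, labels)`.
#' @export
augment_2d <- function(slice, labels, seed) {
  fl <- local_seed(seed, stats::runif(2) < 0.5)
  list(slice = flip_mat(slice, fl[1], fl[2]),
       labels = flip_mat(labels, fl[1], fl[2]))
}

flip_arr <- function(a, fl) {
  d <- dim(a)
  if (fl[1]) a <- a[rev(seq_len(d[1])), , , drop = FALSE]
  if (fl[2]) a <- a[, rev(seq_len(d[2])), , drop = FALSE]
  if (fl[3]) a <- a[, , rev(seq_len(d[3])), drop = FALSE]
  a
}

#' Random flip + cut-out augmentation for a 3D patch
#'
#' Axis flips (probability 1/2 per axis) are applied jointly to image and
#' labels; cut-out then zeroes one random axis-aligned box in the image
#' only, with box edge lengths `max(1, round(dim * cutout_frac^(1/3)))` so
#' the box volume approximates `cutout_frac` of the patch volume. Labels
#' (or pseudo-labels) are never cut. Deterministic given `seed`.
#'
#' @param patch 3D numeric array.
#' @param labels 3D integer array (labels or pseudo-labels).
#' @param seed Integer seed.
#' @param cutout Logical switch for the cut-out.
#' @param cutout_frac Target box volume fraction.
#' @return `list(patch, labels)`.
#' @export
augment_3d <- function(patch, labels, seed, cutout = TRUE, cutout_frac = 0.1) {
  d <- dim(patch)
  local_seed(seed, {
    fl <- stats::runif(3) < 0.5
    patch <- flip_arr(patch, fl)
    labels <- flip_arr(labels, fl)
    if (cutout) {
      len <- pmax(1L, as.integer(round(d * cutout_frac^(1 / 3))))
      o <- vapply(1:3, function(a) sample.int(d[a] - len[a] + 1L, 1L), integer(1))
      patch[o[1] + seq_len(len[1]) - 1L, o[2] + seq_len(len[2]) - 1L,
            o[3] + seq_len(len[3]) - 1L] <- 0
    }
    list(patch = patch, labels = labels)
  })
}

#' Edge lengths of the cut-out box used by [augment_3d()]
#' @param d Integer patch dimensions.
#' @param cutout_frac Target volume fraction.
#' @return Integer length-3 vector.
#' @export
cutout_box_dims <- function(d, cutout_frac = 0.1) {
  pmax(1L, as.integer(round(d * cutout_frac^(1 / 3))))
}

# --- SGD on nested parameter lists ---------------------------------------

tree_zero <- function(p) if (is.list(p)) lapply(p, tree_zero) else p * 0

# Gradient trees may list their leaves in a different order than the
# parameter tree (backward passes build them output-first), so recursion
# matches children by name where names exist, by position otherwise.
tree_child <- function(tree, parent_names, i) {
  if (!is.null(parent_names) && nzchar(parent_names[i])) tree[[parent_names[i]]]
  else tree[[i]]
}

tree_add <- function(a, b) {
  if (!is.list(a)) return(a + b)
  nms <- names(a)
  out <- a
  for (i in seq_along(a)) out[[i]] <- tree_add(a[[i]], tree_child(b, nms, i))
  out
}

sgd_step <- function(pars, grads, vel, lr, mom) {
  if (!is.list(pars)) {
    v <- mom * vel - lr * grads
    return(list(pars = pars + v, vel = v))
  }
  nms <- names(pars)
  for (i in seq_along(pars)) {
    res <- sgd_step(pars[[i]], tree_child(grads, nms, i), vel[[i]], lr, mom)
    pars[[i]] <- res$pars
    vel[[i]] <- res$vel
  }
  list(pars = pars, vel = vel)
}

# Generic epoch loop with poly LR, periodic validation, best-checkpoint
# selection and exact early stopping: training halts `patience` epochs
# after the last validation improvement, and never exceeds max_epochs.
run_epochs <- function(model, run_epoch, validate, cfg) {
  vel <- tree_zero(model$params)
  dice0 <- validate(model)
  best <- list(dice = dice0, model = model, epoch = 0L)
  since <- 0L
  hist <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- poly_lr(epoch - 1L, cfg)
    st <- run_epoch(model, vel, lr, epoch)
    model <- st$model
    vel <- st$vel
    val_dice <- NA_real_
    improved <- FALSE
    if (epoch %% cfg$val_every == 0L || epoch == cfg$max_epochs) {
      val_dice <- validate(model)
      if (val_dice > best$dice) {
        best <- list(dice = val_dice, model = model, epoch = epoch)
        improved <- TRUE
      }
    }
    since <- if (improved) 0L else since + 1L
    hist[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                    l_ce = st$l_ce, l_dice = st$l_dice,
                                    l_sup = st$l_sup, l_un = st$l_un,
                                    l_total = st$l_total, val_dice = val_dice)
    if (since >= cfg$patience) break
  }
  list(model = best$model, best_dice = best$dice, best_epoch = best$epoch,
       dice_epoch0 = dice0, history = do.call(rbind, hist))
}

# Slices (with label slices) from the sliding-window patches of the
# labeled cohort volumes: the step-1 training set.
labeled_slice_set <- function(cohort, cfg) {
  out <- list()
  for (pair in cohort$labeled) {
    vp <- crop_patches(pair$volume, cfg$window, cfg$stride)
    lp <- crop_patches(pair$mask$labels, cfg$window, cfg$stride)
    for (i in seq_along(vp)) {
      vs <- get_slices(vp[[i]])
      ls <- get_slices(lp[[i]])
      for (k in seq_along(vs$slices)) {
        out[[length(out) + 1L]] <- list(x = vs$slices[[k]], y = ls$slices[[k]])
      }
    }
  }
  out
}

# Patch pairs (image, labels) from the labeled cohort volumes.
labeled_patch_set <- function(cohort, cfg) {
  out <- list()
  for (pair in cohort$labeled) {
    vp <- crop_patches(pair$volume, cfg$window, cfg$stride)
    lp <- crop_patches(pair$mask$labels, cfg$window, cfg$stride)
    for (i in seq_along(vp)) {
      out[[length(out) + 1L]] <- list(x = vp[[i]]$data, y = lp[[i]]$data,
                                      case_id = vp[[i]]$case_id,
                                      origin = vp[[i]]$origin)
    }
  }
  out
}

mdcseg_fit <- function(model, res, step, cfg) {
  structure(list(model = res$model, best_dice = res$best_dice,
                 best_epoch = res$best_epoch, dice_epoch0 = res$dice_epoch0,
                 history = res$history, step = step, config = cfg),
            class = "mdcseg_fit")
}

#' Step 1: train the 2D slice network on labeled slices
#'
#' Slices come from the sliding-window patches of the densely labeled
#' training volumes; the loss is the compound supervised loss
#' (`alpha * CE + (1 - alpha) * Dice`). Validation Dice is computed on the
#' cohort's validation volumes by slice-wise patch inference, stitching,
#' argmax, and the labeled-slice restriction.
#'
#' @param cohort An `mdcseg_cohort` with non-empty `labeled`.
#' @param cfg An `mdcseg_train_config`; `cfg$window[1:2]` must match the
#'   model input size.
#' @param model Optionally a pre-initialised `mdcseg_net2d` (default: tiny
#'   preset sized to the window, seeded from `cfg$seed`).
#' @return An `mdcseg_fit` holding the best-validation checkpoint and the
#'   per-epoch loss history.
#' @export
train_step1 <- function(cohort, cfg, model = NULL) {
  stopifnot(inherits(cohort, "mdcseg_cohort"))
  if (!length(cohort$labeled)) stop("cohort has no labeled training volumes")
  if (is.null(model)) {
    model <- net2d_init(net2d_config(input_size = cfg$window[1:2]), seed = cfg$seed)
  }
  ds <- labeled_slice_set(cohort, cfg)
  w <- loss_weights(cfg$alpha, cfg$dice_smooth)
  hw <- model$config$input_size
  run_epoch <- function(model, vel, lr, epoch) {
    n_steps <- cfg$steps_per_epoch %||% ceiling(length(ds) / cfg$batch_size)
    ord <- sample(rep_len(sample.int(length(ds)), n_steps * cfg$batch_size))
    acc <- c(l_ce = 0, l_dice = 0, l_sup = 0)
    for (s in seq_len(n_steps)) {
      idx <- ord[(s - 1L) * cfg$batch_size + seq_len(cfg$batch_size)]
      xb <- array(0, c(hw[1], hw[2], 1L, length(idx), 1L))
      yb <- array(0L, c(hw[1], hw[2], 1L, length(idx)))
      for (j in seq_along(idx)) {
        it <- ds[[idx[j]]]
        if (cfg$augment_flip) {
          it <- augment_2d(it$x, it$y, seed = sample.int(2^30, 1))
          it <- list(x = it$slice, y = it$labels)
        }
        xb[, , 1L, j, 1L] <- it$x
        yb[, , 1L, j] <- it$y
      }
      fw <- net2d_fwd(model$params, xb, model$config)
      lg <- sup_loss_grad(fw$logits, yb, w)
      gr <- net2d_bwd(model$params, fw$cache, lg$dz, model$config)
      up <- sgd_step(model$params, gr, vel, lr, cfg$momentum)
      model$params <- up$pars
      vel <- up$vel
      acc <- acc + c(lg$l_ce, lg$l_dice, lg$l_sup)
    }
    acc <- acc / n_steps
    list(model = model, vel = vel, l_ce = acc[[1]], l_dice = acc[[2]],
         l_sup = acc[[3]], l_un = NA_real_, l_total = acc[[3]])
  }
  validate <- function(model) {
    if (!length(cohort$validation)) return(0)
    mean(vapply(cohort$validation, function(pair) {
      pred <- infer_volume_2d(model, pair$volume, cfg)
      pr <- restrict_to_labeled_slices(pair$mask, pred)
      seg_metrics(pr$gt, pr$pred)$dice
    }, numeric(1)))
  }
  res <- local_seed(cfg$seed, run_epochs(model, run_epoch, validate, cfg))
  mdcseg_fit(model, res, "step1", cfg)
}

#' Step 2: train the 3D patch network with the consistency loss
#'
#' Each optimization step draws a batch of labeled patches (supervised
#' CE+Dice loss against ground truth) and, when unlabeled patches exist, a
#' same-size batch of unlabeled patches (Dice-only loss against their
#' frozen pseudo-labels); gradients of `L_total = L_sup + L_un` update the
#' 3D network. Pseudo-labels are constants: no gradient reaches the 2D
#' network. With no unlabeled data this reduces exactly to supervised
#' training.
#'
#' @param cohort An `mdcseg_cohort`.
#' @param pseudo Pseudo-label set from [pseudo_label_cohort()] (may be
#'   empty/`NULL` when the cohort has no unlabeled volumes or for a
#'   supervised-only baseline).
#' @param cfg An `mdcseg_train_config`; `cfg$window` must match the model
#'   input size.
#' @param model Optionally a pre-initialised `mdcseg_net3d`.
#' @param use_unsupervised Set `FALSE` to train the supervised-only
#'   baseline (ignores `pseudo` and the unlabeled volumes).
#' @return An `mdcseg_fit` with the best-validation checkpoint.
#' @export
train_step2 <- function(cohort, pseudo = NULL, cfg, model = NULL,
                        use_unsupervised = TRUE) {
  stopifnot(inherits(cohort, "mdcseg_cohort"))
  if (!length(cohort$labeled)) stop("cohort has no labeled training volumes")
  if (is.null(model)) {
    model <- net3d_init(net3d_config(input_size = cfg$window), seed = cfg$seed)
  }
  lab <- labeled_patch_set(cohort, cfg)
  w <- loss_weights(cfg$alpha, cfg$dice_smooth)
  wd <- cfg$window
  un <- list()
  if (use_unsupervised && length(cohort$unlabeled)) {
    if (is.null(pseudo)) stop("missing pseudo-labels for unlabeled volumes")
    need <- unlist(lapply(cohort$unlabeled, function(v) {
      vapply(crop_patches(v, cfg$window, cfg$stride), patch_key, character(1))
    }))
    have <- vapply(pseudo$labels, function(pl) {
      patch_key(list(case_id = pl$case_id, origin = pl$origin))
    }, character(1))
    miss <- setdiff(need, have)
    if (length(miss)) {
      stop("missing pseudo-labels for patches: ", paste(miss, collapse = ", "))
    }
    lut <- stats::setNames(seq_along(have), have)
    for (v in cohort$unlabeled) {
      for (p in crop_patches(v, cfg$window, cfg$stride)) {
        pl <- pseudo$labels[[lut[[patch_key(p)]]]]
        un[[length(un) + 1L]] <- list(x = p$data, y = pl$labels)
      }
    }
  }
  make_batch <- function(set, idx, augment) {
    xb <- array(0, c(wd, length(idx), 1L))
    yb <- array(0L, c(wd, length(idx)))
    for (j in seq_along(idx)) {
      it <- set[[idx[j]]]
      if (augment) {
        ag <- augment_3d(it$x, it$y, seed = sample.int(2^30, 1),
                         cutout = cfg$augment_cutout, cutout_frac = cfg$cutout_frac)
        it <- list(x = ag$patch, y = ag$labels)
      }
      xb[, , , j, 1L] <- it$x
      yb[, , , j] <- it$y
    }
    list(x = xb, y = yb)
  }
  run_epoch <- function(model, vel, lr, epoch) {
    n_steps <- cfg$steps_per_epoch %||% ceiling(length(lab) / cfg$batch_size)
    acc <- c(l_ce = 0, l_dice = 0, l_sup = 0, l_un = 0)
    for (s in seq_len(n_steps)) {
      bl <- make_batch(lab, sample.int(length(lab), cfg$batch_size, replace = TRUE),
                       augment = cfg$augment_flip)
      fw <- net3d_fwd(model$params, bl$x, model$config)
      lg <- sup_loss_grad(fw$logits, bl$y, w)
      gr <- net3d_bwd(model$params, fw$cache, lg$dz, model$config)
      l_un <- 0
      if (length(un)) {
        bu <- make_batch(un, sample.int(length(un), cfg$batch_size, replace = TRUE),
                         augment = cfg$augment_flip)
        fwu <- net3d_fwd(model$params, bu$x, model$config)
        lu <- un_loss_grad(fwu$logits, bu$y, cfg$dice_smooth)
        gr <- tree_add(gr, net3d_bwd(model$params, fwu$cache, lu$dz, model$config))
        l_un <- lu$l_un
      }
      up <- sgd_step(model$params, gr, vel, lr, cfg$momentum)
      model$params <- up$pars
      vel <- up$vel
      acc <- acc + c(lg$l_ce, lg$l_dice, lg$l_sup, l_un)
    }
    acc <- acc / n_steps
    list(model = model, vel = vel, l_ce = acc[[1]], l_dice = acc[[2]],
         l_sup = acc[[3]], l_un = if (length(un)) acc[[4]] else NA_real_,
         l_total = acc[[3]] + acc[[4]])
  }
  validate <- function(model) {
    if (!length(cohort$validation)) return(0)
    mean(vapply(cohort$validation, function(pair) {
      pred <- infer_volume(model, pair$volume, cfg)
      pr <- restrict_to_labeled_slices(pair$mask, pred)
      seg_metrics(pr$gt, pr$pred)$dice
    }, numeric(1)))
  }
  res <- local_seed(cfg$seed + 1L, run_epochs(model, run_epoch, validate, cfg))
  mdcseg_fit(model, res, "step2", cfg)
}

#' @export
print.mdcseg_fit <- function(x, ...) {
  cat(sprintf("<mdcseg_fit %s> best val Dice %.4f at epoch %d (%d epochs run)\n",
              x$step, x$best_dice, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' Per-epoch training history of a fit
#' @param x An `mdcseg_fit`.
#' @param ... Unused.
#' @return Tibble with epoch, learning rate, loss components and
#'   validation Dice.
#' @export
tidy.mdcseg_fit <- function(x, ...) x$history

#' One-row summary of a fit
#' @param x An `mdcseg_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.mdcseg_fit <- function(x, ...) {
  tibble::tibble(step = x$step, best_val_dice = x$best_dice,
                 best_epoch = x$best_epoch, epochs_run = nrow(x$history),
                 n_params = n_params(x$model))
}
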