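# Inference and evaluation.
#
# Whole-volume inference crops the sliding-window patches, runs the 3D
# network (or the 2D network slice-wise), averages overlapping patch
# probabilities by stitching, and takes the argmax. Metrics (Dice,
# precision, recall on the foreground class) are computed on the labeled
# slices only — predictions outside a sparse mask's annotated slices never
# influence any number. Multi-seed experiments are aggregated the standard
# way: per-case mean over seeds, then mean and SD over cases; paired
# methods are compared with the Wilcoxon signed-rank test on per-case Dice.

batched_forward_3d <- function(model, patch_list, batch = 4L) {
  wd <- model$config$input_size
  out <- vector("list", length(patch_list))
  i <- 1L
  while (i <= length(patch_list)) {
    idx <- i:min(i + batch - 1L, length(patch_list))
    xb <- array(0, c(wd, length(idx)))
    for (j in seq_along(idx)) xb[, , , j] <- patch_list[[idx[j]]]$data
    pb <- forward_3d(model, xb)
    for (j in seq_along(idx)) out[[idx[j]]] <- pb[, , , j, ]
    i <- i + batch
  }
  out
}

#' Segment a volume with the 3D patch network
#'
#' `argmax(stitch(forward_3d(crop_patches(v))))` with mean-probability
#' fusion in the overlaps and ties to background; deterministic.
#'
#' @param model3d A trained `mdcseg_net3d`.
#' @param v An `mdcseg_volume` (or 3D array).
#' @param cfg An `mdcseg_train_config` providing window/stride.
#' @return 3D integer array of predicted labels, the volume's shape.
#' @export
infer_volume <- function(model3d, v, cfg) {
  stopifnot(inherits(model3d, "mdcseg_net3d"))
  patches <- crop_patches(v, cfg$window, cfg$stride)
  probs <- batched_forward_3d(model3d, patches, batch = cfg$batch_size)
  preds <- lapply(seq_along(patches), function(i) {
    list(origin = patches[[i]]$origin, prob = probs[[i]])
  })
  argmax_labels(stitch(preds, attr(patches, "vol_dim")))
}

#' Segment a volume with the 2D slice network (slice-wise patch inference)
#'
#' Each patch is split into axial slices, every slice goes through the 2D
#' network, the slice probabilities are merged back into the patch and the
#' patches are stitched; used for step-1 validation and for comparing the
#' two networks on equal footing.
#'
#' @param model2d A trained `mdcseg_net2d`.
#' @param v An `mdcseg_volume` (or 3D array).
#' @param cfg An `mdcseg_train_config` providing window/stride.
#' @return 3D integer array of predicted labels.
#' @export
infer_volume_2d <- function(model2d, v, cfg) {
  stopifnot(inherits(model2d, "mdcseg_net2d"))
  patches <- crop_patches(v, cfg$window, cfg$stride)
  preds <- lapply(patches, function(p) {
    list(origin = p$origin, prob = forward_2d(model2d, p$data))
  })
  argmax_labels(stitch(preds, attr(patches, "vol_dim")))
}

#' Foreground Dice, precision and recall from paired label vectors
#'
#' Counted on the foreground class: `dice = 2TP/(2TP+FP+FN)`,
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`. When ground truth and
#' prediction are both empty all three are defined as 1; an empty
#' denominator against a non-empty counterpart gives 0.
#'
#' @param gt,pred Equal-length integer vectors with values in \{0, 1\}.
#' @return `list(dice, precision, recall)`, each in \[0, 1\].
#' @export
seg_metrics <- function(gt, pred) {
  if (length(gt) != length(pred)) stop("gt and pred must have equal length")
  if (length(gt) && any(c(gt, pred) != 0L & c(gt, pred) != 1L)) {
    stop("labels must lie in {0, 1}")
  }
  tp <- sum(gt == 1L & pred == 1L)
  fp <- sum(gt == 0L & pred == 1L)
  fn <- sum(gt == 1L & pred == 0L)
  list(dice = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
       precision = if (tp + fp == 0) { if (fn == 0) 1 else 0 } else tp / (tp + fp),
       recall = if (tp + fn == 0) { if (fp == 0) 1 else 0 } else tp / (tp + fn))
}

#' Evaluate one case under the sparse-slice rule
#'
#' Runs [infer_volume()] and computes [seg_metrics()] on the
#' [restrict_to_labeled_slices()] pairing only, so predictions on
#' unlabeled slices cannot change any metric.
#'
#' @param model3d A trained `mdcseg_net3d`.
#' @param v An `mdcseg_volume`.
#' @param m Its `mdcseg_label_mask`.
#' @param cfg An `mdcseg_train_config`.
#' @return One-row tibble: `case_id`, `dice`, `precision`, `recall`.
#' @export
evaluate_case <- function(model3d, v, m, cfg) {
  pred <- infer_volume(model3d, v, cfg)
  pr <- restrict_to_labeled_slices(m, pred)
  sm <- seg_metrics(pr$gt, pr$pred)
  tibble::tibble(case_id = v$case_id, dice = sm$dice,
                 precision = sm$precision, recall = sm$recall)
}

#' Evaluate every test case of a cohort
#'
#' @param model3d A trained `mdcseg_net3d`.
#' @param cohort An `mdcseg_cohort`.
#' @param cfg An `mdcseg_train_config`.
#' @param which Which case list to evaluate (`"test"` or `"validation"`).
#' @return Tibble with one row per case.
#' @export
evaluate_cohort <- function(model3d, cohort, cfg, which = c("test", "validation")) {
  which <- match.arg(which)
  do.call(rbind, lapply(cohort[[which]], function(pair) {
    evaluate_case(model3d, pair$volume, pair$mask, cfg)
  }))
}

#' Aggregate per-seed, per-case metrics into a report
#'
#' Each case's final value is the mean of its per-seed values; the report
#' then gives the mean and standard deviation across cases.
#'
#' @param per_seed List of per-case metric tibbles (one per seed), as
#'   returned by [evaluate_cohort()]; cases are matched by `case_id`.
#' @return An `mdcseg_metrics` report: `per_case` tibble (seed-averaged),
#'   `summary` tibble (mean and SD over cases per metric), `n_cases`,
#'   `n_seeds`.
#' @export
aggregate_seeds <- function(per_seed) {
  stopifnot(length(per_seed) >= 1L)
  ids <- sort(per_seed[[1]]$case_id)
  for (tb in per_seed) {
    if (!identical(sort(tb$case_id), ids)) stop("seeds must cover identical cases")
  }
  per_case <- do.call(rbind, lapply(ids, function(id) {
    rows <- do.call(rbind, lapply(per_seed, function(tb) tb[tb$case_id == id, ]))
    tibble::tibble(case_id = id, dice = mean(rows$dice),
                   precision = mean(rows$precision), recall = mean(rows$recall))
  }))
  summ <- do.call(rbind, lapply(c("dice", "precision", "recall"), function(mm) {
    tibble::tibble(metric = mm, mean = mean(per_case[[mm]]),
                   sd = stats::sd(per_case[[mm]]))
  }))
  structure(list(per_case = per_case, summary = summ,
                 n_cases = length(ids), n_seeds = length(per_seed)),
            class = "mdcseg_metrics")
}

#' @export
print.mdcseg_metrics <- function(x, ...) {
  cat(sprintf("<mdcseg_metrics> %d case(s), %d seed(s)\n", x$n_cases, x$n_seeds))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Per-case metrics of a report
#' @param x An `mdcseg_metrics` report.
#' @param ... Unused.
#' @return The seed-averaged per-case tibble.
#' @export
tidy.mdcseg_metrics <- function(x, ...) x$per_case

#' One-row summary of a metrics report
#' @param x An `mdcseg_metrics` report.
#' @param ... Unused.
#' @return One-row tibble with mean/SD per metric.
#' @export
glance.mdcseg_metrics <- function(x, ...) {
  s <- x$summary
  tibble::tibble(dice_mean = s$mean[s$metric == "dice"],
                 dice_sd = s$sd[s$metric == "dice"],
                 precision_mean = s$mean[s$metric == "precision"],
                 precision_sd = s$sd[s$metric == "precision"],
                 recall_mean = s$mean[s$metric == "recall"],
                 recall_sd = s$sd[s$metric == "recall"],
                 n_cases = x$n_cases, n_seeds = x$n_seeds)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's original procedure). For up to
#' 12 non-zero differences the p-value is computed by exact enumeration of
#' all `2^n` sign assignments over the (tie-averaged) ranks of the
#' absolute differences; for larger n the normal approximation with tie
#' correction is used. If every difference is zero the test is degenerate
#' and p = 1 by convention.
#'
#' @param a,b Equal-length numeric vectors of paired per-case scores.
#' @return `list(p_value, statistic, n)` where `statistic` is the
#'   positive-rank sum W+ and `n` the number of non-zero differences.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(p_value = 1, statistic = NA_real_, n = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wd <- as.vector(signs %*% r)
    p <- 2 * min(mean(Wd <= W), mean(Wd >= W))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(p_value = min(p, 1), statistic = W, n = n)
}
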