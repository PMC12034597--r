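# Pseudo-label generation.
#
# The trained 2D slice network labels the unlabeled patches: each patch is
# split into its axial slices, every slice is pushed through the network,
# the per-slice probability maps are merged back into a patch-shaped
# probability grid, and argmax (ties to background) yields the discrete
# pseudo-label. Pseudo-labels are computed once after step-1 training and
# frozen: they are plain integer arrays, cached on disk keyed by
# (case id, origin, checkpoint fingerprint), and carry no gradient path
# back to the 2D network.

patch_key <- function(p) {
  sprintf("%s_%d_%d_%d", p$case_id, p$origin[1], p$origin[2], p$origin[3])
}

#' Deterministic fingerprint of a model's weights
#'
#' A cheap content checksum over the flattened parameters (and the config),
#' used to key pseudo-label caches so that a changed checkpoint invalidates
#' them.
#'
#' @param model An `mdcseg_net2d` or `mdcseg_net3d`.
#' @return Character scalar.
#' @export
model_fingerprint <- function(model) {
  x <- unlist(model$params, use.names = FALSE)
  sprintf("%d-%s-%s", length(x),
          format(sum(x * seq_along(x)) %% 1e9, digits = 12),
          format(sum(x^2) %% 1e9, digits = 12))
}

#' Pseudo-label one patch with the 2D slice network
#'
#' Equals `argmax(merge_slices(forward_2d(get_slices(p))))`, with argmax
#' ties broken toward background; deterministic given the weights.
#'
#' @param model2d A trained `mdcseg_net2d`.
#' @param p An `mdcseg_patch` (slice shape must match the model input).
#' @return An `mdcseg_pseudo_label`: integer `labels` in \{0, 1\} of the
#'   patch's shape, plus `origin`, `case_id` and `source_checkpoint`.
#' @export
pseudo_label_patch <- function(model2d, p) {
  stopifnot(inherits(model2d, "mdcseg_net2d"), inherits(p, "mdcseg_patch"))
  probs <- forward_2d(model2d, p$data)  # z axis doubles as the batch axis
  structure(list(labels = argmax_labels(probs), origin = p$origin,
                 case_id = p$case_id,
                 source_checkpoint = model_fingerprint(model2d)),
            class = "mdcseg_pseudo_label")
}

#' Pseudo-label all unlabeled patches of a cohort, with an on-disk cache
#'
#' One pseudo-label per patch; cache entries are keyed by
#' (case id, origin, checkpoint fingerprint), so re-running with the same
#' checkpoint recomputes nothing and a different checkpoint invalidates
#' every entry.
#'
#' @param model2d A trained `mdcseg_net2d`.
#' @param cohort An `mdcseg_cohort` (its `unlabeled` volumes are labeled),
#'   or a plain list of `mdcseg_patch` objects.
#' @param cfg An `mdcseg_train_config` (for window/stride); ignored when
#'   patches are passed directly.
#' @param cache_dir Directory for cached labels (created if missing);
#'   `NULL` disables caching.
#' @return `list(labels, checkpoint, n_computed, n_cached)` where `labels`
#'   is a list of `mdcseg_pseudo_label`s in patch enumeration order.
#' @export
pseudo_label_cohort <- function(model2d, cohort, cfg = NULL, cache_dir = NULL) {
  patches <- if (inherits(cohort, "mdcseg_cohort")) {
    stopifnot(!is.null(cfg))
    unlist(lapply(cohort$unlabeled, crop_patches,
                  window = cfg$window, stride = cfg$stride),
           recursive = FALSE)
  } else cohort
  ckpt <- model_fingerprint(model2d)
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  n_computed <- 0L
  n_cached <- 0L
  labels <- vector("list", length(patches))
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    f <- if (!is.null(cache_dir)) {
      file.path(cache_dir, paste0(patch_key(p), "_", ckpt, ".rds"))
    } else NULL
    if (!is.null(f) && file.exists(f)) {
      labels[[i]] <- readRDS(f)
      n_cached <- n_cached + 1L
    } else {
      labels[[i]] <- pseudo_label_patch(model2d, p)
      n_computed <- n_computed + 1L
      if (!is.null(f)) saveRDS(labels[[i]], f)
    }
  }
  list(labels = labels, checkpoint = ckpt,
       n_computed = n_computed, n_cached = n_cached)
}
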