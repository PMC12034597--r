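# ggplot2-based views of fits and metric reports (ggplot2 is suggested,
# not required; these error informatively when it is absent).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
}

#' Plot training loss curves and validation Dice of a fit
#'
#' @param object An `mdcseg_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mdcseg_fit <- function(object, ...) {
  need_ggplot()
  h <- object$history
  long <- do.call(rbind, lapply(c("l_sup", "l_un", "l_total"), function(nm) {
    tibble::tibble(epoch = h$epoch, series = nm, value = h[[nm]])
  }))
  long <- long[!is.na(long$value), ]
  vd <- h[!is.na(h$val_dice), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = tibble::tibble(epoch = vd$epoch,
                                              series = "val_dice",
                                              value = vd$val_dice)) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = sprintf("%s training (best val Dice %.3f)",
                                  object$step, object$best_dice))
}

#' Plot per-case Dice of a paired experiment
#'
#' @param object An `mdcseg_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mdcseg_experiment <- function(object, ...) {
  need_ggplot()
  d <- object$per_seed
  ggplot2::ggplot(d, ggplot2::aes(x = .data$arm, y = .data$dice)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$seed)),
                        position = ggplot2::position_jitter(width = 0.08),
                        alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "test Dice (labeled slices)",
                  colour = "seed",
                  title = sprintf("two-step vs supervised baseline (Wilcoxon p = %.3f)",
                                  object$wilcoxon$p_value))
}

#' Show an axial slice of a volume with optional label overlay
#'
#' @param v An `mdcseg_volume`.
#' @param z 1-based axial slice index.
#' @param mask Optional `mdcseg_label_mask` or 3D label array whose
#'   foreground contour is overlaid.
#' @return A ggplot object.
#' @export
plot_slice <- function(v, z, mask = NULL) {
  need_ggplot()
  arr <- if (inherits(v, "mdcseg_volume")) v$intensities else v
  sl <- arr[, , z]
  df <- tibble::tibble(x = rep(seq_len(nrow(sl)), ncol(sl)),
                       y = rep(seq_len(ncol(sl)), each = nrow(sl)),
                       value = as.vector(sl))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("axial slice z = %d", z), fill = NULL)
  if (!is.null(mask)) {
    lab <- if (inherits(mask, "mdcseg_label_mask")) mask$labels else mask
    mf <- df
    mf$fg <- as.vector(lab[, , z])
    p <- p + ggplot2::geom_contour(data = mf,
                                   ggplot2::aes(z = .data$fg),
                                   breaks = 0.5, colour = "red")
  }
  p
}
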