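# Sliding-window patches, axial slice stacks, and stitching.
#
# Origins are 1-based voxel coordinates. The origin lattice per axis is
# {1, 1+s, 1+2s, ...} plus one clamped origin at (dim - w + 1) whenever the
# lattice does not already end there, so every voxel is covered. When a
# volume dimension is smaller than the window the volume is zero-padded at
# the high end up to the window size. Patches are enumerated z-major (z
# slowest, then y, then x), a fixed order that makes pseudo-label caches
# reproducible. Overlapping patch predictions are fused by arithmetic mean
# of probabilities before any argmax.

axis_origins <- function(dim, w, s) {
  if (w > dim) stop("window larger than grid after padding policy")
  og <- seq(1L, dim - w + 1L, by = s)
  last <- dim - w + 1L
  if (og[length(og)] != last) og <- c(og, last)
  og
}

#' Extract sliding-window patches from a volume
#'
#' @param v An `mdcseg_volume` or a plain 3D array.
#' @param window Integer `c(wx, wy, wz)` patch size.
#' @param stride Integer `c(sx, sy, sz)` lattice stride (components >= 1).
#' @return List of `mdcseg_patch` objects (`data`, 1-based `origin`,
#'   `case_id`), with attributes `vol_dim` (original grid) and `padded_dim`.
#' @export
crop_patches <- function(v, window, stride) {
  arr <- if (inherits(v, "mdcseg_volume")) v$intensities else v
  case_id <- if (inherits(v, "mdcseg_volume")) v$case_id else "array"
  window <- as.integer(window); stride <- as.integer(stride)
  stopifnot(length(window) == 3L, length(stride) == 3L, all(stride >= 1L),
            length(dim(arr)) == 3L)
  d <- dim(arr)
  pd <- pmax(d, window)
  if (any(pd > d)) {
    tmp <- array(0, pd)
    tmp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
    arr <- tmp
  }
  og <- lapply(1:3, function(a) axis_origins(pd[a], window[a], stride[a]))
  grid <- expand.grid(x = og[[1]], y = og[[2]], z = og[[3]])  # x fastest, z slowest
  patches <- lapply(seq_len(nrow(grid)), function(i) {
    o <- as.integer(grid[i, ])
    structure(list(data = arr[o[1] + seq_len(window[1]) - 1L,
                              o[2] + seq_len(window[2]) - 1L,
                              o[3] + seq_len(window[3]) - 1L, drop = FALSE],
                   origin = o, case_id = case_id),
              class = "mdcseg_patch")
  })
  attr(patches, "vol_dim") <- d
  attr(patches, "padded_dim") <- pd
  patches
}

#' Split a patch into its axial slices
#'
#' Slice `k` equals `p$data[, , k]`; `z_offsets` are 0-based offsets
#' relative to the patch origin.
#'
#' @param p An `mdcseg_patch` or a 3D array.
#' @return An `mdcseg_slice_stack` with `slices` (list of 2D matrices) and
#'   `z_offsets` (`0:(wz-1)`).
#' @export
get_slices <- function(p) {
  arr <- if (inherits(p, "mdcseg_patch")) p$data else p
  wz <- dim(arr)[3]
  structure(list(slices = lapply(seq_len(wz), function(k) arr[, , k]),
                 z_offsets = seq_len(wz) - 1L),
            class = "mdcseg_slice_stack")
}

#' Merge a slice stack back into a 3D grid
#'
#' Stacks the slices along z in `z_offsets` order; the inverse of
#' [get_slices()], bit-exactly.
#'
#' @param s An `mdcseg_slice_stack` (slices may be listed in any order as
#'   long as `z_offsets` says where each belongs).
#' @return 3D array of shape `(wx, wy, wz)`.
#' @export
merge_slices <- function(s) {
  stopifnot(inherits(s, "mdcseg_slice_stack"))
  shp <- dim(s$slices[[1]])
  if (!all(vapply(s$slices, function(m) identical(dim(m), shp), logical(1)))) {
    stop("ragged slice shapes: all slices must share one 2D shape")
  }
  wz <- length(s$slices)
  out <- array(0, c(shp, wz))
  ord <- order(s$z_offsets)
  for (i in seq_along(ord)) out[, , i] <- s$slices[[ord[i]]]
  out
}

#' Stitch per-patch probability maps into a full-volume probability map
#'
#' Each voxel's probability vector is the arithmetic mean over all patches
#' containing it, renormalised to sum to 1. Errors if any voxel of the
#' volume is covered by no patch, naming the uncovered region.
#'
#' @param pred_patches List of `list(origin, prob)` where `prob` is a 4D
#'   `(wx, wy, wz, classes)` probability array and `origin` the patch's
#'   1-based origin.
#' @param vol_dim Integer `c(nx, ny, nz)` of the target volume.
#' @return 4D array `(nx, ny, nz, classes)` of class probabilities.
#' @export
stitch <- function(pred_patches, vol_dim) {
  stopifnot(length(pred_patches) >= 1L, length(vol_dim) == 3L)
  vol_dim <- as.integer(vol_dim)
  C <- dim(pred_patches[[1]]$prob)[4]
  for (pp in pred_patches) {
    if (dim(pp$prob)[4] != C) stop("all patch probability maps must share one class count")
  }
  pd <- vol_dim
  for (pp in pred_patches) {
    pd <- pmax(pd, pp$origin + dim(pp$prob)[1:3] - 1L)
  }
  prob_sum <- array(0, c(pd, C))
  count <- array(0, pd)
  for (pp in pred_patches) {
    o <- pp$origin
    w <- dim(pp$prob)[1:3]
    ix <- o[1] + seq_len(w[1]) - 1L
    iy <- o[2] + seq_len(w[2]) - 1L
    iz <- o[3] + seq_len(w[3]) - 1L
    prob_sum[ix, iy, iz, ] <- prob_sum[ix, iy, iz, , drop = FALSE] + pp$prob
    count[ix, iy, iz] <- count[ix, iy, iz] + 1
  }
  count <- count[seq_len(vol_dim[1]), seq_len(vol_dim[2]), seq_len(vol_dim[3]),
                 drop = FALSE]
  prob_sum <- prob_sum[seq_len(vol_dim[1]), seq_len(vol_dim[2]),
                       seq_len(vol_dim[3]), , drop = FALSE]
  if (any(count == 0)) {
    miss <- which(count == 0, arr.ind = TRUE)
    stop(sprintf("uncovered voxels: x %d..%d, y %d..%d, z %d..%d",
                 min(miss[, 1]), max(miss[, 1]), min(miss[, 2]), max(miss[, 2]),
                 min(miss[, 3]), max(miss[, 3])))
  }
  n <- prod(vol_dim)
  pm <- prob_sum
  dim(pm) <- c(n, C)
  pm <- pm / as.vector(count)
  pm <- pm / rowSums(pm)
  dim(pm) <- c(vol_dim, C)
  pm
}

#' Argmax labels from a probability map
#'
#' Ties are broken toward the lower class index (background), so an exact
#' (0.5, 0.5) voxel is labeled 0.
#'
#' @param prob Array whose last axis is the class axis.
#' @return Integer array of class indices in `0..(classes-1)`, dropping the
#'   class axis.
#' @export
argmax_labels <- function(prob) {
  d <- dim(prob)
  C <- d[length(d)]
  n <- prod(d[-length(d)])
  pm <- prob
  dim(pm) <- c(n, C)
  lab <- max.col(pm, ties.method = "first") - 1L
  array(as.integer(lab), d[-length(d)])
}
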