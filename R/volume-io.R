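# Volumes, label masks and cohorts.
#
# A Volume is a 3D scalar grid indexed (x, y, z) with z the axial
# direction, plus its voxel spacing in mm and a case id. A LabelMask pairs
# a binary {0,1} label grid with the explicit set of axial slice indices
# that actually carry ground truth: a labeled slice can legitimately
# contain no foreground, so labeled slices are never inferred from slice
# content. Slice indices are 1-based throughout, the native R convention.
#
# Density kinds mirror the clinical cohort structure: "dense" volumes are
# annotated on (essentially) every slice, "sparse" volumes on a small set
# of discontinuous slices (metrics are later restricted to those), and
# "unlabeled" volumes carry no annotation at all.

#' Construct a volume
#'
#' @param intensities 3D numeric array, indexed (x, y, z), z axial.
#' @param spacing Numeric length-3 voxel spacing `(sx, sy, sz)` in mm.
#' @param case_id Character scalar identifier.
#' @return An `mdcseg_volume` object.
#' @export
volume <- function(intensities, spacing = c(1, 1, 1), case_id = "case") {
  d <- dim(intensities)
  if (is.null(d) || length(d) != 3L) stop("non-3D input: intensities must be a 3D array")
  if (any(d < 1L)) stop("all grid dimensions must be >= 1")
  stopifnot(length(spacing) == 3L, all(spacing > 0), is.character(case_id),
            length(case_id) == 1L)
  structure(list(intensities = intensities, spacing = as.numeric(spacing),
                 case_id = case_id),
            class = "mdcseg_volume")
}

#' Construct a label mask
#'
#' @param labels 3D integer array with values in \{0, 1\} (0 background,
#'   1 foreground), same shape as the paired volume.
#' @param labeled_slices Integer vector of 1-based axial (z) slice indices
#'   that carry ground truth.
#' @param density One of `"dense"`, `"sparse"`, `"unlabeled"`.
#' @return An `mdcseg_label_mask` object.
#' @export
label_mask <- function(labels,
                       labeled_slices = seq_len(dim(labels)[3]),
                       density = c("dense", "sparse", "unlabeled")) {
  density <- match.arg(density)
  d <- dim(labels)
  if (is.null(d) || length(d) != 3L) stop("non-3D input: labels must be a 3D array")
  if (any(labels != 0L & labels != 1L)) stop("label values must lie in {0, 1}")
  labeled_slices <- sort(unique(as.integer(labeled_slices)))
  if (length(labeled_slices) &&
      (min(labeled_slices) < 1L || max(labeled_slices) > d[3])) {
    stop("labeled_slices out of the valid z range")
  }
  if (density == "unlabeled" && length(labeled_slices)) {
    stop("an unlabeled mask cannot have labeled slices")
  }
  structure(list(labels = array(as.integer(labels), d),
                 labeled_slices = labeled_slices, density = density),
            class = "mdcseg_label_mask")
}

#' Construct a cohort
#'
#' The case-level split the pipeline trains and evaluates on: densely
#' labeled training volumes, unlabeled training volumes, and validation /
#' test volumes with (possibly sparse) masks. Case ids must be disjoint
#' across the four lists.
#'
#' @param labeled List of `list(volume, mask)` pairs with dense masks.
#' @param unlabeled List of volumes.
#' @param validation,test Lists of `list(volume, mask)` pairs.
#' @return An `mdcseg_cohort` object.
#' @export
cohort <- function(labeled = list(), unlabeled = list(),
                   validation = list(), test = list()) {
  ids <- c(vapply(labeled, function(p) p$volume$case_id, character(1)),
           vapply(unlabeled, function(v) v$case_id, character(1)),
           vapply(validation, function(p) p$volume$case_id, character(1)),
           vapply(test, function(p) p$volume$case_id, character(1)))
  if (anyDuplicated(ids)) stop("case ids must be disjoint across cohort lists")
  for (p in labeled) {
    if (p$mask$density != "dense") stop("labeled training masks must be dense")
  }
  structure(list(labeled = labeled, unlabeled = unlabeled,
                 validation = validation, test = test),
            class = "mdcseg_cohort")
}

#' @export
print.mdcseg_volume <- function(x, ...) {
  cat(sprintf("<volume '%s'> %s voxels @ %s mm\n", x$case_id,
              paste(dim(x$intensities), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.mdcseg_label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %s, %s, %d labeled slice(s)\n",
              paste(dim(x$labels), collapse = "x"), x$density,
              length(x$labeled_slices)))
  invisible(x)
}

#' @export
print.mdcseg_cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d labeled + %d unlabeled train, %d validation, %d test\n",
              length(x$labeled), length(x$unlabeled),
              length(x$validation), length(x$test)))
  invisible(x)
}

# --- NIfTI IO ------------------------------------------------------------

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a volume from a NIfTI file
#'
#' Spacing is taken from the file header (`pixdim`); intensities are not
#' modified. The case id defaults to the file stem unless a sidecar JSON
#' written by [write_volume()] provides one.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return An `mdcseg_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path, "': ",
                                           conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("non-3D input: '", path, "' has ", length(dim(arr)), " dimensions")
  }
  arr <- array(as.vector(arr), dim(arr))  # drop NIfTI header attributes
  spacing <- RNifti::pixdim(img)[1:3]
  case_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    if (!is.null(meta$case_id)) case_id <- meta$case_id
  }
  volume(arr, spacing, case_id)
}

#' Write a volume to a NIfTI file (plus a sidecar JSON with the case id)
#'
#' @param v An `mdcseg_volume`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "mdcseg_volume"))
  img <- RNifti::asNifti(v$intensities)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(case_id = v$case_id), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a label mask (NIfTI labels + sidecar JSON)
#'
#' The sidecar JSON written by [write_label_mask()] carries `density` and
#' the 1-based `labeled_slices`.
#'
#' @param path Path to the mask `.nii` / `.nii.gz` file.
#' @return An `mdcseg_label_mask`.
#' @export
read_label_mask <- function(path) {
  v <- read_volume(path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar JSON for label mask: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  label_mask(array(as.integer(round(v$intensities)), dim(v$intensities)),
             labeled_slices = as.integer(meta$labeled_slices %||% integer()),
             density = meta$density)
}

#' Write a label mask (NIfTI labels + sidecar JSON)
#'
#' @param m An `mdcseg_label_mask`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param spacing Voxel spacing recorded in the NIfTI header.
#' @param case_id Case id recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(m, path, spacing = c(1, 1, 1), case_id = "case") {
  stopifnot(inherits(m, "mdcseg_label_mask"))
  img <- RNifti::asNifti(m$labels)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(case_id = case_id, density = m$density,
                            labeled_slices = m$labeled_slices),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- resampling ----------------------------------------------------------

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Per-axis source coordinates (0-based, voxel centers aligned at 0) for an
# output axis of length n_out at spacing target over a source axis of
# length n_in at spacing s_in.
axis_coords <- function(n_out, target, s_in, n_in) {
  pmin(pmax((seq_len(n_out) - 1) * target / s_in, 0), n_in - 1)
}

trilinear_resample <- function(arr, coords) {
  d <- dim(arr)
  lo <- lapply(seq_len(3), function(a) {
    i0 <- pmin(floor(coords[[a]]), d[a] - 1 - (d[a] > 1))
    i0 <- pmax(i0, 0)
    list(i0 = i0 + 1, f = coords[[a]] - i0)
  })
  nx <- length(coords[[1]]); ny <- length(coords[[2]]); nz <- length(coords[[3]])
  out <- array(0, c(nx, ny, nz))
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wx <- if (a == 0) 1 - lo[[1]]$f else lo[[1]]$f
    wy <- if (b == 0) 1 - lo[[2]]$f else lo[[2]]$f
    wz <- if (cc == 0) 1 - lo[[3]]$f else lo[[3]]$f
    w <- array(wx, c(nx, ny, nz)) * rep(wy, each = nx) * rep(wz, each = nx * ny)
    ix <- pmin(lo[[1]]$i0 + a, d[1]); iy <- pmin(lo[[2]]$i0 + b, d[2])
    iz <- pmin(lo[[3]]$i0 + cc, d[3])
    out <- out + w * arr[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Resample a volume (and optionally its mask) to isotropic spacing
#'
#' Intensities are interpolated trilinearly; labels with nearest-neighbour
#' interpolation so values stay in \{0, 1\}. Output grid dimensions are
#' `round(dim * spacing / target_mm)` with round-half-away-from-zero. A
#' sparse mask's labeled slices map to the output slices whose nearest
#' source slice was labeled.
#'
#' @param v An `mdcseg_volume`.
#' @param m Optional paired `mdcseg_label_mask` (or `NULL`).
#' @param target_mm Positive target spacing in mm (default 1).
#' @return `list(volume, mask)`; `mask` is `NULL` when `m` was.
#' @export
resample_isotropic <- function(v, m = NULL, target_mm = 1) {
  stopifnot(inherits(v, "mdcseg_volume"))
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0) {
    stop("target_mm must be a positive scalar")
  }
  d <- dim(v$intensities)
  if (all(abs(v$spacing - target_mm) < 1e-12)) {
    return(list(volume = volume(v$intensities, rep(target_mm, 3), v$case_id),
                mask = m))
  }
  nd <- pmax(as.integer(round_half_away(d * v$spacing / target_mm)), 1L)
  coords <- lapply(1:3, function(a) axis_coords(nd[a], target_mm, v$spacing[a], d[a]))
  out_v <- volume(trilinear_resample(v$intensities, coords),
                  rep(target_mm, 3), v$case_id)
  out_m <- NULL
  if (!is.null(m)) {
    stopifnot(inherits(m, "mdcseg_label_mask"))
    if (!all(dim(m$labels) == d)) stop("mask shape does not match volume shape")
    nn <- lapply(1:3, function(a) pmin(pmax(round(coords[[a]]) + 1, 1), d[a]))
    lab <- m$labels[nn[[1]], nn[[2]], nn[[3]], drop = FALSE]
    new_slices <- if (length(m$labeled_slices)) {
      which(nn[[3]] %in% m$labeled_slices)
    } else integer()
    out_m <- label_mask(lab, new_slices, m$density)
  }
  list(volume = out_v, mask = out_m)
}

#' Restrict paired ground truth and prediction to labeled slices
#'
#' Returns the voxels of the mask's labeled axial slices only, flattened in
#' a fixed deterministic order (x fastest, then y, then labeled slices in
#' increasing z). This is the pairing all sparse-slice metrics are computed
#' on.
#'
#' @param m An `mdcseg_label_mask`.
#' @param prediction 3D integer array of predicted labels, same shape as
#'   `m$labels`.
#' @return `list(gt, pred)` of equal-length integer vectors (empty when no
#'   slice is labeled).
#' @export
restrict_to_labeled_slices <- function(m, prediction) {
  stopifnot(inherits(m, "mdcseg_label_mask"))
  if (!all(dim(prediction) == dim(m$labels))) {
    stop("prediction shape does not match labels shape")
  }
  zs <- m$labeled_slices
  list(gt = as.integer(m$labels[, , zs]),
       pred = as.integer(prediction[, , zs]))
}
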