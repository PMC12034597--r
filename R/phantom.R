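# Synthetic tubular phantoms.
#
# The generator emulates the structure of a contrast-poor abdominal CT
# cohort at desk scale: bright tubular foreground of varying radius and
# curvature (folded-bowel-like), nearby confounder blobs whose intensity is
# within +/-10% of the tubes' (neighboring-organ contact) but which are
# background in the labels, additive Gaussian intensity noise, and the
# dense / sparse / unlabeled annotation split. Everything is a pure
# function of (spec, seed).

#' Specification for a synthetic tubular phantom
#'
#' @param grid_size Integer `c(nx, ny, nz)`, each >= 16.
#' @param n_tubes Number of tubular foreground structures.
#' @param tube_radius_range `c(min, max)` tube radius in voxels.
#' @param tube_intensity Foreground intensity (arbitrary units).
#' @param background_intensity Background intensity.
#' @param n_confounders Number of confounder ellipsoids (label 0, intensity
#'   within +/-10% of `tube_intensity`); when tubes exist, the first one is
#'   placed touching a tube.
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param seed Integer seed; phantoms are deterministic given the spec.
#' @param fg_fraction_range Acceptable band for the foreground voxel
#'   fraction; geometry is redrawn (bounded retries) until the fraction
#'   falls inside it, mimicking clinical class imbalance.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_size = c(64L, 64L, 32L), n_tubes = 2L,
                         tube_radius_range = c(3, 5), tube_intensity = 1,
                         background_intensity = 0, n_confounders = 2L,
                         noise_sd = 0, seed = 1L,
                         fg_fraction_range = c(0.01, 0.15)) {
  stopifnot(length(grid_size) == 3L, all(grid_size >= 16L),
            n_tubes >= 0L, length(tube_radius_range) == 2L,
            tube_radius_range[1] > 0,
            tube_radius_range[2] >= tube_radius_range[1],
            2 * tube_radius_range[2] < min(grid_size),
            noise_sd >= 0, n_confounders >= 0L,
            length(fg_fraction_range) == 2L)
  structure(list(grid_size = as.integer(grid_size), n_tubes = as.integer(n_tubes),
                 tube_radius_range = as.numeric(tube_radius_range),
                 tube_intensity = tube_intensity,
                 background_intensity = background_intensity,
                 n_confounders = as.integer(n_confounders),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 fg_fraction_range = as.numeric(fg_fraction_range)),
            class = "phantom_spec")
}

# Smooth random-walk centerline: a few control points joined by cubic
# splines, clamped to keep the dilated tube inside the grid.
tube_centerline <- function(d, margin) {
  npts <- 7L
  lo <- rep(margin + 1, 3)
  hi <- d - margin
  ctrl <- matrix(0, npts, 3)
  ctrl[1, ] <- stats::runif(3, lo, hi)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  step <- max(4, min(d) / 3)
  for (i in 2:npts) {
    dir <- dir + 0.7 * stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    ctrl[i, ] <- pmin(pmax(ctrl[i - 1, ] + step * dir, lo), hi)
  }
  tt <- seq(1, npts, by = 0.01)
  cl <- vapply(1:3, function(a) stats::spline(seq_len(npts), ctrl[, a], xout = tt)$y,
               numeric(length(tt)))
  cl[, 1] <- pmin(pmax(cl[, 1], lo[1]), hi[1])
  cl[, 2] <- pmin(pmax(cl[, 2], lo[2]), hi[2])
  cl[, 3] <- pmin(pmax(cl[, 3], lo[3]), hi[3])
  cl
}

ball_offsets <- function(r) {
  rg <- seq(-ceiling(r), ceiling(r))
  g <- as.matrix(expand.grid(rg, rg, rg))
  g[rowSums(g^2) <= r^2, , drop = FALSE]
}

# Set label 1 inside the Euclidean-ball dilation of a polyline.
stamp_tube <- function(lab, cl, r) {
  d <- dim(lab)
  ctr <- round(cl)
  offs <- ball_offsets(r)
  vox <- cbind(rep(ctr[, 1], each = nrow(offs)) + offs[, 1],
               rep(ctr[, 2], each = nrow(offs)) + offs[, 2],
               rep(ctr[, 3], each = nrow(offs)) + offs[, 3])
  ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 & vox[, 2] <= d[2] &
    vox[, 3] >= 1 & vox[, 3] <= d[3]
  vox <- vox[ok, , drop = FALSE]
  lab[vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)] <- 1L
  lab
}

ellipsoid_voxels <- function(center, semi, d) {
  rg <- lapply(1:3, function(a) {
    seq(max(1L, floor(center[a] - semi[a])), min(d[a], ceiling(center[a] + semi[a])))
  })
  g <- as.matrix(expand.grid(rg[[1]], rg[[2]], rg[[3]]))
  u <- sweep(g, 2, center)
  u <- sweep(u, 2, semi, "/")
  g[rowSums(u^2) <= 1, , drop = FALSE]
}

phantom_draw <- function(spec, case_id) {
  d <- spec$grid_size
  lab <- array(0L, d)
  margin <- ceiling(spec$tube_radius_range[2]) + 1
  tubes <- vector("list", spec$n_tubes)
  for (t in seq_len(spec$n_tubes)) {
    r <- stats::runif(1, spec$tube_radius_range[1], spec$tube_radius_range[2])
    cl <- tube_centerline(d, margin)
    lab <- stamp_tube(lab, cl, r)
    tubes[[t]] <- list(cl = cl, r = r)
  }
  intens <- array(spec$background_intensity, d)
  intens[lab == 1L] <- spec$tube_intensity
  for (k in seq_len(spec$n_confounders)) {
    semi <- stats::runif(3, 2, 5)
    if (k == 1L && spec$n_tubes > 0L) {
      # place the first confounder touching a tube surface
      tb <- tubes[[sample.int(spec$n_tubes, 1)]]
      p <- tb$cl[sample.int(nrow(tb$cl), 1), ]
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      center <- pmin(pmax(p + u * (tb$r + min(semi)), 1), d)
    } else {
      center <- stats::runif(3, 1 + semi, d - semi)
    }
    vox <- ellipsoid_voxels(center, semi, d)
    if (nrow(vox)) {
      li <- vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)
      li <- li[lab[li] == 0L]
      intens[li] <- spec$tube_intensity * stats::runif(1, 0.9, 1.1)
    }
  }
  if (spec$noise_sd > 0) {
    intens <- intens + stats::rnorm(length(intens), 0, spec$noise_sd)
    dim(intens) <- d
  }
  list(volume = volume(intens, c(1, 1, 1), case_id),
       mask = label_mask(lab, seq_len(d[3]), "dense"))
}

#' Generate a phantom volume and its dense label mask
#'
#' Deterministic given `spec` (which includes the seed). The geometry is
#' redrawn up to 20 times until the foreground fraction falls inside
#' `spec$fg_fraction_range`; if it never does, an error names the violated
#' constraint.
#'
#' @param spec A [phantom_spec()].
#' @param case_id Case id for the generated volume.
#' @return `list(volume, mask)` with a dense mask (all slices labeled).
#' @export
make_phantom <- function(spec, case_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  frac <- NA_real_
  for (attempt in seq_len(20L)) {
    res <- local_seed(spec$seed + 7919L * (attempt - 1L),
                      phantom_draw(spec, case_id))
    frac <- mean(res$mask$labels)
    if (frac >= spec$fg_fraction_range[1] && frac <= spec$fg_fraction_range[2]) {
      return(res)
    }
  }
  stop(sprintf(paste0("infeasible geometry: foreground fraction %.4f outside ",
                      "fg_fraction_range [%.3f, %.3f] after 20 redraws"),
               frac, spec$fg_fraction_range[1], spec$fg_fraction_range[2]))
}

#' Sparsify a dense label mask
#'
#' Keeps the label content but marks only a uniformly sampled subset of
#' `max(1, round(fraction * nz))` axial slices as labeled, mirroring
#' sparsely annotated clinical volumes (a few percent of slices).
#'
#' @param m A dense `mdcseg_label_mask`.
#' @param fraction Fraction of slices to keep, in (0, 1].
#' @param seed Integer seed for the slice draw.
#' @return A sparse `mdcseg_label_mask` (density `"sparse"`; or `"dense"`
#'   unchanged when `fraction = 1`).
#' @export
sparsify_labels <- function(m, fraction, seed = 1L) {
  stopifnot(inherits(m, "mdcseg_label_mask"))
  if (m$density != "dense") stop("sparsify_labels expects a dense mask")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  nz <- dim(m$labels)[3]
  if (fraction == 1) return(m)
  k <- max(1L, as.integer(round_half_away(fraction * nz)))
  keep <- local_seed(seed, sort(sample.int(nz, k)))
  label_mask(m$labels, keep, "sparse")
}

#' Generate a full phantom cohort
#'
#' Draws `n_labeled` densely labeled training volumes, `n_unlabeled`
#' unlabeled training volumes and `n_val` / `n_test` evaluation volumes
#' from independent per-case seeds derived deterministically from `seed`,
#' so the cohort is reproducible and stable under list reordering.
#'
#' @param n_labeled,n_unlabeled,n_val,n_test Non-negative case counts.
#' @param spec A [phantom_spec()] (its own `seed` field is ignored here).
#' @param seed Master seed for the cohort.
#' @param eval_density `"sparse"` or `"dense"` masks for validation/test
#'   cases.
#' @param sparse_fraction Labeled-slice fraction for sparse evaluation
#'   masks (default 0.05, a few percent of slices).
#' @return An `mdcseg_cohort`.
#' @export
make_cohort <- function(n_labeled, n_unlabeled, n_val, n_test, spec,
                        seed = 1L, eval_density = c("sparse", "dense"),
                        sparse_fraction = 0.05) {
  eval_density <- match.arg(eval_density)
  stopifnot(n_labeled >= 0L, n_unlabeled >= 0L, n_val >= 0L, n_test >= 0L)
  n_all <- n_labeled + n_unlabeled + n_val + n_test
  case_seeds <- local_seed(seed, sample.int(2^30, n_all))
  gen <- function(i, id) {
    sp <- spec
    sp$seed <- case_seeds[i]
    make_phantom(sp, id)
  }
  i <- 0L
  labeled <- lapply(seq_len(n_labeled), function(k) {
    gen(k, sprintf("lab%02d", k))
  })
  unlabeled <- lapply(seq_len(n_unlabeled), function(k) {
    gen(n_labeled + k, sprintf("unl%02d", k))$volume
  })
  evalize <- function(p, i) {
    if (eval_density == "sparse") {
      p$mask <- sparsify_labels(p$mask, sparse_fraction, seed = case_seeds[i] + 1L)
    }
    p
  }
  validation <- lapply(seq_len(n_val), function(k) {
    i <- n_labeled + n_unlabeled + k
    evalize(gen(i, sprintf("val%02d", k)), i)
  })
  test <- lapply(seq_len(n_test), function(k) {
    i <- n_labeled + n_unlabeled + n_val + k
    evalize(gen(i, sprintf("tst%02d", k)), i)
  })
  cohort(labeled = labeled, unlabeled = unlabeled,
         validation = validation, test = test)
}
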