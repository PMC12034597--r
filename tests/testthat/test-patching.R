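brute_force_origins <- function(dim, w, s) {
  og <- unique(c(seq(1L, dim - w + 1L, by = s), dim - w + 1L))
  sort(og)
}

test_that("the clinical-scale window/stride yields the expected 8 patches", {
  arr <- array(0, c(384, 384, 24))
  ps <- crop_patches(arr, c(256L, 256L, 16L), c(128L, 128L, 8L))
  expect_length(ps, 8L)
  got <- t(sapply(ps, function(p) p$origin))
  want <- as.matrix(expand.grid(x = c(1L, 129L), y = c(1L, 129L),
                                z = c(1L, 9L)))
  expect_equal(unname(got), unname(want))
})

test_that("origin lattices clamp at the boundary and cover every voxel", {
  arr <- array(seq_len(60 * 52 * 20), c(60, 52, 20))
  w <- c(32L, 32L, 16L)
  s <- c(16L, 16L, 8L)
  ps <- crop_patches(arr, w, s)
  ox <- sort(unique(sapply(ps, function(p) p$origin[1])))
  expect_equal(ox, brute_force_origins(60L, 32L, 16L))  # 1, 17, 29 (clamped)
  cover <- array(0L, dim(arr))
  for (p in ps) {
    ix <- p$origin[1] + seq_len(w[1]) - 1L
    iy <- p$origin[2] + seq_len(w[2]) - 1L
    iz <- p$origin[3] + seq_len(w[3]) - 1L
    cover[ix, iy, iz] <- cover[ix, iy, iz] + 1L
    expect_identical(p$data, arr[ix, iy, iz])
  }
  expect_true(all(cover >= 1L))

  # random small grids: every voxel in at least one patch
  set.seed(5)
  for (i in 1:5) {
    d <- sample(10:40, 3)
    a <- array(0, d)
    wr <- pmin(c(8L, 8L, 4L), d)
    pr <- crop_patches(a, wr, c(5L, 3L, 2L))
    cov <- array(0L, d)
    for (p in pr) {
      cov[p$origin[1] + seq_len(wr[1]) - 1L, p$origin[2] + seq_len(wr[2]) - 1L,
          p$origin[3] + seq_len(wr[3]) - 1L] <- 1L
    }
    expect_true(all(cov == 1L))
  }
})

test_that("a grid equal to the window gives one patch at the origin", {
  arr <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  ps <- crop_patches(arr, c(8L, 8L, 4L), c(4L, 4L, 2L))
  expect_length(ps, 1L)
  expect_equal(ps[[1]]$origin, c(1L, 1L, 1L))
  expect_identical(ps[[1]]$data, arr)
})

test_that("grids smaller than the window are zero-padded up to it", {
  arr <- array(1, c(6, 6, 3))
  ps <- crop_patches(arr, c(8L, 8L, 4L), c(8L, 8L, 4L))
  expect_length(ps, 1L)
  expect_equal(dim(ps[[1]]$data), c(8L, 8L, 4L))
  expect_equal(sum(ps[[1]]$data), 6 * 6 * 3)
  expect_error(crop_patches(arr, c(8L, 8L, 4L), c(0L, 1L, 1L)))
})

test_that("a 256x256x16 patch splits into sixteen 256x256 slices", {
  p <- crop_patches(array(rnorm(256 * 256 * 16), c(256, 256, 16)),
                    c(256L, 256L, 16L), c(128L, 128L, 8L))[[1]]
  s <- get_slices(p)
  expect_length(s$slices, 16L)
  expect_equal(dim(s$slices[[1]]), c(256L, 256L))
  expect_equal(s$z_offsets, 0:15)
  expect_identical(s$slices[[5]], p$data[, , 5])
})

test_that("merge_slices inverts get_slices bit-exactly and honours offsets", {
  arr <- array(rnorm(8 * 6 * 5), c(8, 6, 5))
  s <- get_slices(arr)
  expect_identical(merge_slices(s), arr)

  perm <- sample(5)
  s2 <- structure(list(slices = s$slices[perm], z_offsets = s$z_offsets[perm]),
                  class = "mdcseg_slice_stack")
  expect_identical(merge_slices(s2), arr)

  s3 <- s
  s3$slices[[2]] <- matrix(0, 4, 6)
  expect_error(merge_slices(s3), "ragged")
})

test_that("stitching averages probabilities in overlaps", {
  mk <- function(p1, w) {
    pr <- array(0, c(w, 2))
    pr[, , , 1] <- 1 - p1
    pr[, , , 2] <- p1
    pr
  }
  w <- c(4L, 4L, 2L)
  # two patches overlapping on x 5..8 of a 12-wide volume
  a <- list(origin = c(1L, 1L, 1L), prob = mk(0.8, w))
  b <- list(origin = c(5L, 1L, 1L), prob = mk(0.4, w))
  cpatch <- list(origin = c(9L, 1L, 1L), prob = mk(0.4, w))
  st <- stitch(list(a, list(origin = c(5L, 1L, 1L), prob = mk(0.4, w)),
                    cpatch), c(12L, 4L, 2L))
  expect_equal(st[2, 2, 1, ], c(0.2, 0.8))
  expect_equal(st[6, 2, 1, ], c(0.6, 0.4))  # only patch b and c region? no: b only
  expect_equal(dim(st), c(12L, 4L, 2L, 2L))
  expect_true(all(abs(apply(st, 1:3, sum) - 1) < 1e-12))

  # identical constant probabilities stay constant under overlap
  ov <- stitch(list(a, list(origin = c(3L, 1L, 1L), prob = mk(0.8, w))),
               c(6L, 4L, 2L))
  expect_true(all(abs(ov[, , , 2] - 0.8) < 1e-12))

  # hand arithmetic: (0.2, 0.8) and (0.6, 0.4) average to (0.4, 0.6)
  ov2 <- stitch(list(a, list(origin = c(3L, 1L, 1L), prob = mk(0.4, w))),
                c(6L, 4L, 2L))
  expect_equal(ov2[3, 1, 1, ], c(0.4, 0.6))
  expect_equal(ov2[4, 2, 2, ], c(0.4, 0.6))

  # single covering patch is the identity
  pr <- array(stats::runif(4 * 4 * 2), c(4, 4, 2))
  one <- array(0, c(4, 4, 2, 2))
  one[, , , 2] <- pr
  one[, , , 1] <- 1 - pr
  expect_equal(stitch(list(list(origin = c(1L, 1L, 1L), prob = one)),
                      c(4L, 4L, 2L)), one)

  expect_error(stitch(list(a), c(12L, 4L, 2L)), "uncovered")
})

test_that("one-hot ground truth survives crop/stitch/argmax exactly", {
  set.seed(8)
  ph <- make_phantom(micro_spec(seed = 21L), "gt")
  lab <- ph$mask$labels
  w <- c(16L, 16L, 8L)
  s <- c(8L, 8L, 4L)
  ps <- crop_patches(lab, w, s)
  preds <- lapply(ps, function(p) {
    pr <- array(0, c(w, 2L))
    pr[, , , 1] <- 1 - p$data
    pr[, , , 2] <- p$data
    list(origin = p$origin, prob = pr)
  })
  st <- stitch(preds, dim(lab))
  out <- argmax_labels(st)
  expect_identical(out, lab)
  expect_equal(seg_metrics(as.integer(lab), as.integer(out))$dice, 1)
})

test_that("argmax breaks ties toward background", {
  pr <- array(0.5, c(2, 2, 1, 2))
  expect_true(all(argmax_labels(pr) == 0L))
  pr[1, 1, 1, ] <- c(0.4, 0.6)
  expect_equal(argmax_labels(pr)[1, 1, 1], 1L)
})
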