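test_that("forward passes emit normalized per-element class probabilities", {
  m2 <- net2d_init(net2d_config(), seed = 1L)
  x <- matrix(rnorm(32 * 32), 32, 32)
  p <- forward_2d(m2, x)
  expect_equal(dim(p), c(32L, 32L, 2L))
  expect_true(all(abs(p[, , 1] + p[, , 2] - 1) < 1e-5))
  expect_true(all(p >= 0 & p <= 1))

  xb <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  pb <- forward_2d(m2, xb)
  expect_equal(dim(pb), c(32L, 32L, 3L, 2L))
  expect_equal(pb[, , 2, ], forward_2d(m2, xb[, , 2]), tolerance = 1e-12)

  m3 <- net3d_init(net3d_config(), seed = 1L)
  x3 <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
  p3 <- forward_3d(m3, x3)
  expect_equal(dim(p3), c(32L, 32L, 8L, 2L))
  expect_true(all(abs(p3[, , , 1] + p3[, , , 2] - 1) < 1e-5))
})

test_that("networks are pure functions of weights and input", {
  m2 <- net2d_init(net2d_config(), seed = 2L)
  x <- matrix(rnorm(32 * 32), 32, 32)
  expect_identical(forward_2d(m2, x), forward_2d(m2, x))
  m3 <- net3d_init(net3d_config(), seed = 2L)
  x3 <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
  expect_identical(forward_3d(m3, x3), forward_3d(m3, x3))
  # no baked-in symmetry: flipping the input changes an untrained output
  xf <- x3[rev(seq_len(32)), , ]
  expect_false(isTRUE(all.equal(forward_3d(m3, xf)[rev(seq_len(32)), , , ],
                                forward_3d(m3, x3))))
})

test_that("input shape mismatches raise errors", {
  m2 <- net2d_init(net2d_config(), seed = 1L)
  expect_error(forward_2d(m2, matrix(0, 16, 16)), "input size")
  m3 <- net3d_init(net3d_config(), seed = 1L)
  expect_error(forward_3d(m3, array(0, c(16, 16, 8))), "input size")
  expect_error(net2d_config(input_size = c(30, 30)), "divisible")
  expect_error(net3d_config(input_size = c(30, 32, 8)), "divisible")
  expect_error(net3d_config(n_classes = 1L))
})

test_that("parameter counts grow with width and init is seed-deterministic", {
  n_small <- n_params(net2d_init(net2d_config(embed_dim = 8L), seed = 1L))
  n_big <- n_params(net2d_init(net2d_config(embed_dim = 16L), seed = 1L))
  expect_gt(n_big, 3 * n_small)
  a <- net2d_init(net2d_config(), seed = 7L)
  b <- net2d_init(net2d_config(), seed = 7L)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params,
                         net2d_init(net2d_config(), seed = 8L)$params))
  n3s <- n_params(net3d_init(net3d_config(base_channels = 4L), seed = 1L))
  n3b <- n_params(net3d_init(net3d_config(base_channels = 8L), seed = 1L))
  expect_gt(n3b, 3 * n3s)
})

test_that("compiled convolution agrees with the plain-R reference", {
  set.seed(9)
  x <- array(rnorm(6 * 5 * 4 * 2 * 3), c(6, 5, 4, 2, 3))
  for (k in list(c(3L, 3L, 3L), c(3L, 3L, 1L), c(1L, 1L, 1L))) {
    W <- array(rnorm(prod(k) * 3 * 2), c(prod(k), 3, 2))
    b <- rnorm(2)
    got <- mdcseg:::conv_fwd(x, W, b, k)
    ref <- mdcseg:::conv_fwd_ref(x, W, b, k)
    expect_equal(got$out, ref$out, tolerance = 1e-12)
    dy <- array(rnorm(length(got$out)), dim(got$out))
    bg <- mdcseg:::conv_bwd(got, dy, W, k)
    br <- mdcseg:::conv_bwd_ref(ref, dy, W, k)
    expect_equal(bg$dx, br$dx, tolerance = 1e-12)
    expect_equal(as.vector(bg$dW), as.vector(br$dW), tolerance = 1e-12)
    expect_equal(bg$db, br$db, tolerance = 1e-12)
  }
})

test_that("network gradients match finite differences", {
  set.seed(10)
  w <- loss_weights()
  modify <- function(ps, path, i, d) {
    if (!length(path)) { ps[i] <- ps[i] + d; return(ps) }
    k <- suppressWarnings(as.integer(path[1]))
    key <- if (!is.na(k)) k else path[1]
    ps[[key]] <- modify(ps[[key]], path[-1], i, d)
    ps
  }
  pluck <- function(tr, path) {
    for (nm in path) {
      k <- suppressWarnings(as.integer(nm))
      tr <- tr[[if (!is.na(k)) k else nm]]
    }
    tr
  }
  # 2D network
  cfg2 <- tiny_net2d_config()
  m2 <- net2d_init(cfg2, seed = 3L)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2, 1))
  y <- array(sample(0:1, 8 * 8 * 2, TRUE), c(8, 8, 1, 2))
  f2 <- function(pars) {
    lg <- mdcseg:::net2d_fwd(pars, x, cfg2, with_cache = FALSE)$logits
    mdcseg:::sup_loss_grad(lg, y, w)$l_sup
  }
  fw <- mdcseg:::net2d_fwd(m2$params, x, cfg2)
  gr <- mdcseg:::net2d_bwd(m2$params, fw$cache,
                           mdcseg:::sup_loss_grad(fw$logits, y, w)$dz, cfg2)
  for (path in list(c("stem", "W"), c("att1", "Wq"), c("att2", "g"),
                    c("enc2", "W"), c("dec0c", "W"), c("head", "W"))) {
    g <- pluck(gr, path)
    p <- pluck(m2$params, path)
    for (i in sample(length(p), min(2, length(p)))) {
      num <- (f2(modify(m2$params, path, i, 1e-5)) -
                f2(modify(m2$params, path, i, -1e-5))) / 2e-5
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
  # 3D network
  cfg3 <- net3d_config(base_channels = 2L, n_levels = 3L,
                       input_size = c(8L, 8L, 4L))
  m3 <- net3d_init(cfg3, seed = 4L)
  x3 <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2, 1))
  y3 <- array(sample(0:1, 8 * 8 * 4 * 2, TRUE), c(8, 8, 4, 2))
  f3 <- function(pars) {
    lg <- mdcseg:::net3d_fwd(pars, x3, cfg3, with_cache = FALSE)$logits
    mdcseg:::sup_loss_grad(lg, y3, w)$l_sup
  }
  fw3 <- mdcseg:::net3d_fwd(m3$params, x3, cfg3)
  gr3 <- mdcseg:::net3d_bwd(m3$params, fw3$cache,
                            mdcseg:::sup_loss_grad(fw3$logits, y3, w)$dz, cfg3)
  for (path in list(c("enc", "1", "a", "W"), c("enc", "3", "b", "W"),
                    c("dec", "1", "c", "W"), c("dec", "2", "a", "W"),
                    c("head", "b"))) {
    g <- pluck(gr3, path)
    p <- pluck(m3$params, path)
    for (i in sample(length(p), min(2, length(p)))) {
      num <- (f3(modify(m3$params, path, i, 1e-5)) -
                f3(modify(m3$params, path, i, -1e-5))) / 2e-5
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})
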