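test_that("poly schedule hits its endpoints and decreases strictly", {
  cfg <- train_config(max_epochs = 500L, lr0 = 0.01, poly_power = 0.9)
  expect_equal(poly_lr(0, cfg), 0.01)
  expect_equal(poly_lr(500, cfg), 0)
  expect_equal(poly_lr(250, cfg), 0.01 * 0.5^0.9)
  lrs <- vapply(0:500, poly_lr, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) < 0))
  expect_error(poly_lr(-1, cfg), "range")
  expect_error(poly_lr(501, cfg), "range")
})

test_that("2D flip augmentation is a seeded involution preserving counts", {
  set.seed(1)
  sl <- matrix(rnorm(64), 8, 8)
  lb <- matrix(sample(0:1, 64, TRUE), 8, 8)
  a <- augment_2d(sl, lb, seed = 5L)
  b <- augment_2d(sl, lb, seed = 5L)
  expect_identical(a, b)
  expect_equal(sum(a$labels), sum(lb))
  expect_equal(sort(as.vector(a$slice)), sort(as.vector(sl)))
  # applying the same flips twice returns the original
  aa <- augment_2d(a$slice, a$labels, seed = 5L)
  expect_identical(aa$slice, sl)
  expect_identical(aa$labels, lb)
})

test_that("3D augmentation flips jointly and cuts out only the image", {
  set.seed(2)
  p <- array(rnorm(8 * 8 * 4) + 10, c(8, 8, 4))  # strictly positive
  l <- array(sample(0:1, 256, TRUE), c(8, 8, 4))
  a <- augment_3d(p, l, seed = 3L, cutout = TRUE, cutout_frac = 0.1)
  expect_identical(a, augment_3d(p, l, seed = 3L, cutout = TRUE,
                                 cutout_frac = 0.1))
  expect_equal(sum(a$labels), sum(l))               # labels never cut
  box <- cutout_box_dims(dim(p), 0.1)
  expect_equal(sum(a$patch == 0), prod(box))        # zeros only from cut-out
  nf <- augment_3d(p, l, seed = 3L, cutout = FALSE)
  expect_equal(sort(as.vector(nf$patch)), sort(as.vector(p)))
})

test_that("early stopping halts exactly patience epochs after the last gain", {
  # stub "training" that never changes the model, with a scripted
  # validation trace (first entry is the pre-training epoch-0 check):
  # improvements at epochs 1 and 4, flat afterwards
  trace <- c(0.1, 0.3, 0.3, 0.3, 0.5, rep(0.5, 50))
  e <- new.env()
  e$i <- 0L
  cfg <- train_config(max_epochs = 40L, patience = 3L, val_every = 1L,
                      steps_per_epoch = 1L)
  res <- mdcseg:::run_epochs(
    model = list(params = list(w = 0)),
    run_epoch = function(model, vel, lr, epoch) {
      list(model = model, vel = vel, l_ce = 0, l_dice = 0, l_sup = 0,
           l_un = NA_real_, l_total = 0)
    },
    validate = function(model) {
      e$i <- e$i + 1L
      trace[e$i]
    },
    cfg = cfg)
  # last improvement at epoch 4 -> stops after epoch 7 (patience 3)
  expect_equal(nrow(res$history), 7L)
  expect_equal(res$best_epoch, 4L)
  expect_equal(res$best_dice, 0.5)

  # a frozen model with patience 1 stops after one non-improving epoch
  e$i <- 0L
  cfg1 <- train_config(max_epochs = 40L, patience = 1L, val_every = 1L,
                       steps_per_epoch = 1L)
  res1 <- mdcseg:::run_epochs(
    model = list(params = list(w = 0)),
    run_epoch = function(model, vel, lr, epoch) {
      list(model = model, vel = vel, l_ce = 0, l_dice = 0, l_sup = 0,
           l_un = NA_real_, l_total = 0)
    },
    validate = function(model) 0.4,
    cfg = cfg1)
  expect_equal(nrow(res1$history), 1L)

  # the cap is never exceeded even when validation keeps improving
  e$j <- 0L
  cfgc <- train_config(max_epochs = 5L, patience = 100L, val_every = 1L,
                       steps_per_epoch = 1L)
  resc <- mdcseg:::run_epochs(
    model = list(params = list(w = 0)),
    run_epoch = function(model, vel, lr, epoch) {
      list(model = model, vel = vel, l_ce = 0, l_dice = 0, l_sup = 0,
           l_un = NA_real_, l_total = 0)
    },
    validate = function(model) { e$j <- e$j + 1L; e$j / 100 },
    cfg = cfgc)
  expect_equal(nrow(resc$history), 5L)
})

make_mini_cohort <- function(seed = 31L, n_unlabeled = 1L) {
  make_cohort(1, n_unlabeled, 1, 1, micro_spec(), seed = seed,
              eval_density = "sparse", sparse_fraction = 0.2)
}

mini_cfg <- function(max_epochs = 2L, steps_per_epoch = 3L, ...) {
  train_config(max_epochs = max_epochs, patience = 10L, batch_size = 2L,
               steps_per_epoch = steps_per_epoch, window = c(32L, 32L, 8L),
               stride = c(32L, 32L, 8L), val_every = 1L, seed = 1L, ...)
}

test_that("step-1 training learns and is seed-reproducible", {
  ch <- make_mini_cohort()
  cfg <- mini_cfg(max_epochs = 3L, steps_per_epoch = 6L)
  f1 <- train_step1(ch, cfg)
  expect_s3_class(f1, "mdcseg_fit")
  expect_gte(f1$best_dice, f1$dice_epoch0)
  expect_true(all(diff(f1$history$lr) < 0))
  f1b <- train_step1(ch, cfg)
  expect_identical(f1$history$l_sup, f1b$history$l_sup)
  expect_identical(f1$model$params, f1b$model$params)
  expect_error(train_step1(cohort(), cfg), "no labeled")
})

test_that("step-2 without unlabeled data is exactly supervised training", {
  ch0 <- make_cohort(1, 0, 1, 1, micro_spec(), seed = 32L,
                     sparse_fraction = 0.2)
  cfg <- mini_cfg()
  f <- train_step2(ch0, NULL, cfg)
  expect_true(all(is.na(f$history$l_un)))
  fb <- train_step2(ch0, NULL, cfg, use_unsupervised = FALSE)
  expect_identical(f$model$params, fb$model$params)
})

test_that("step-2 loss log satisfies the total-loss identity", {
  ch <- make_mini_cohort()
  cfg <- mini_cfg()
  f1 <- train_step1(ch, cfg)
  ps <- pseudo_label_cohort(f1$model, ch, cfg)
  f2 <- train_step2(ch, ps, cfg)
  h <- f2$history
  expect_true(all(abs(h$l_total - (h$l_sup + h$l_un)) < 1e-7))
  expect_true(all(abs(h$l_sup - (0.3 * h$l_ce + 0.7 * h$l_dice)) < 1e-7))
})

test_that("step 2 demands a pseudo-label for every unlabeled patch", {
  ch <- make_mini_cohort()
  cfg <- mini_cfg()
  f1 <- train_step1(ch, cfg)
  ps <- pseudo_label_cohort(f1$model, ch, cfg)
  ps$labels <- ps$labels[-1]
  expect_error(train_step2(ch, ps, cfg), "missing pseudo-labels.*unl01")
})
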