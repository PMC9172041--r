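test_that("the default architecture reaches a 6x6 map through doubling filters", {
  cfg <- model_config()
  layers <- spihits:::model_layers(cfg)
  blocks <- layers[grepl("^block", names(layers))]
  expect_length(blocks, 8)
  # channel sequence along the blocks: doubling at each downsampling, capped
  couts <- vapply(blocks, function(b) b$cout, integer(1))
  expect_equal(unname(couts),
               c(32L, 32L, 64L, 64L, 128L, 128L, 256L, 256L))
  # a plan that does not reproduce the final map is rejected
  bad <- model_config(downsample_plan = rep(list(c(1L, 1L)), 8))
  expect_error(build_model(bad), "final map")
})

test_that("forward pass shapes: 6x6 pre-pooling map and B x 2 class scores", {
  m <- build_model(model_config(), seed = 1)
  x <- array(rnorm(192 * 96 * 2), c(192L, 96L, 1L, 2L))
  fw <- spihits:::net_forward(m, x, train = FALSE)
  expect_equal(dim(fw$logits), c(2L, 2L))           # 2 classes x batch
  expect_equal(dim(fw$caches$head$x)[1:3], c(6L, 6L, 256L))
  probs <- spihits:::softmax_cols(fw$logits)
  expect_equal(colSums(probs), rep(1, 2))
})

test_that("backpropagated gradients match numerical differentiation", {
  set.seed(42)
  m <- build_model(tiny_model_config(), seed = 1)
  x <- array(rnorm(8 * 8 * 1 * 3), c(8L, 8L, 1L, 3L))
  y <- c(1L, 0L, 1L)
  w <- c(0.4, 0.6)
  lossfun <- function(mm) {
    fw <- spihits:::net_forward(mm, x, train = TRUE)
    spihits:::weighted_ce(fw$logits, y, w)$loss
  }
  fw <- spihits:::net_forward(m, x, train = TRUE)
  ce <- spihits:::weighted_ce(fw$logits, y, w)
  gr <- spihits:::net_backward(m, fw$caches, ce$dlogits)
  eps <- 1e-5
  for (k in names(m$params)) {
    for (i in sample(length(m$params[[k]]), min(3, length(m$params[[k]])))) {
      m2 <- m; m2$params[[k]][i] <- m2$params[[k]][i] + eps
      m3 <- m; m3$params[[k]][i] <- m3$params[[k]][i] - eps
      num <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
      expect_equal(gr[[k]][i], num, tolerance = 1e-4,
                   label = sprintf("analytic grad of %s[%d]", k, i))
    }
  }
})

test_that("the polynomial schedule starts at lr0, ends at 0, never increases", {
  expect_equal(lr_schedule(0, 50000, 1e-4), 1e-4)
  expect_equal(lr_schedule(50000, 50000, 1e-4), 0)
  expect_equal(lr_schedule(25000, 50000, 1e-4, 0.9), 5.358867e-05,
               tolerance = 1e-6)
  lr <- lr_schedule(0:1000, 1000, 1e-4)
  expect_true(all(diff(lr) <= 0))
  expect_error(lr_schedule(51000, 50000), "\\[0, total\\]")
  expect_error(lr_schedule(-1, 50000), "\\[0, total\\]")
})

test_that("minibatch sampling hits the configured single-hit rate", {
  labels <- c(rep(1L, 20), rep(0L, 980))
  set.seed(3)
  idx <- sample_minibatch(labels, p_single = 0.02, batch_size = 1e5)
  frac <- mean(labels[idx])
  sigma <- sqrt(0.02 * 0.98 / 1e5)
  expect_lt(abs(frac - 0.02), 3 * sigma)
  # p = 1: all singles
  expect_true(all(labels[sample_minibatch(labels, 1, 64L)] == 1L))
  # requested class missing
  expect_error(sample_minibatch(rep(0L, 10), 0.5, 8L), "no single hits")
  expect_error(sample_minibatch(rep(1L, 10), 0.5, 8L), "no non-single")
})

test_that("zero-magnitude augmentation is the identity", {
  cfg <- augment_config(p_geom = 1, rotation_deg = 0, scale_range = c(1, 1),
                        shift_px = 0, p_elastic = 0, p_gamma = 0,
                        p_noise = 0, p_blur = 0, p_mirror = 0, p_cutout = 0)
  set.seed(8)
  patch <- matrix(rnorm(32 * 16), 32, 16)
  expect_equal(augment(patch, cfg), patch, tolerance = 1e-12)
})

test_that("mirroring twice restores the patch; cutout blanks exactly s^2 pixels", {
  set.seed(9)
  patch <- matrix(rexp(32 * 16) + 0.5, 32, 16)  # strictly positive
  mirrored <- patch[32:1, ]
  expect_equal(mirrored[32:1, ], patch)
  cfg <- augment_config(p_geom = 0, p_gamma = 0, p_noise = 0, p_blur = 0,
                        p_mirror = 0, p_cutout = 1, cutout_size = 5L,
                        cutout_fill = 0)
  out <- augment(patch, cfg)
  expect_equal(sum(out == 0), 25)
  expect_equal(dim(out), dim(patch))
})

test_that("equal class weights reduce to plain cross entropy up to a factor", {
  set.seed(12)
  logits <- matrix(rnorm(2 * 16), 2, 16)
  y <- rbinom(16, 1, 0.4)
  plain <- spihits:::weighted_ce(logits, y, c(1, 1))
  halved <- spihits:::weighted_ce(logits, y, c(0.5, 0.5))
  expect_equal(halved$loss, 0.5 * plain$loss, tolerance = 1e-12)
  expect_equal(halved$dlogits, 0.5 * plain$dlogits, tolerance = 1e-12)
})

test_that("training reduces the loss on a separable synthetic set and is seed-deterministic", {
  g <- toy_geometry(c(64L, 64L))
  ds <- generate_dataset(quiet_sim(seed = 31, mean_photon_scale = 3000),
                         g, 25, 175)
  prep <- extract_patches(ds, c(32L, 16L))
  tc <- train_config(batch_size = 16L, epochs = 10L,
                     iterations_per_epoch = 20L, p_single_in_batch = 0.25,
                     seed = 5, augment = NULL)
  set.seed(tc$seed)
  fit <- train_fold(prep$patches, ds$labels, tc, model_config_small())
  expect_lt(mean(tail(fit$loss, 3)), fit$loss[1])
  expect_true(all(is.finite(fit$loss)))
  # same seed, same trace
  tc2 <- train_config(batch_size = 16L, epochs = 2L,
                      iterations_per_epoch = 10L, p_single_in_batch = 0.25,
                      seed = 5, augment = NULL)
  set.seed(tc2$seed)
  f1 <- train_fold(prep$patches, ds$labels, tc2, model_config_small())
  set.seed(tc2$seed)
  f2 <- train_fold(prep$patches, ds$labels, tc2, model_config_small())
  expect_identical(f1$loss, f2$loss)
})

test_that("stratified folds preserve class proportions and partition the data", {
  set.seed(2)
  labels <- c(rep(1L, 100), rep(0L, 19900))
  fold <- spihits:::stratified_folds(labels, 5L)
  for (f in 1:5) {
    expect_equal(sum(fold == f & labels == 1L), 20)
    expect_equal(sum(fold == f & labels == 0L), 3980)
  }
  expect_true(all(fold %in% 1:5))          # every pattern in exactly one fold
  expect_length(fold, 20000)
  expect_error(spihits:::stratified_folds(c(rep(1L, 3), rep(0L, 50)), 5L),
               "fewer members")
})

test_that("training configuration validates its imbalance parameters", {
  expect_error(train_config(p_single_in_batch = 0), "strictly between")
  expect_error(train_config(p_single_in_batch = 1), "strictly between")
  expect_error(train_config(class_loss_weights = c(0, 1)), "positive")
  moresh <- train_config_moresh(epochs = 3L)
  expect_equal(moresh$p_single_in_batch, 0.05)
  expect_equal(moresh$class_loss_weights, c(0.1, 0.9))
  expect_equal(moresh$epochs, 3L)
})
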