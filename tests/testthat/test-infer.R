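# A deterministic two-member "ensemble" built from tiny trained-free models
# gives the inference layer something to chew on without long training.
make_toy_ensemble <- function(n_members = 2, seed = 1) {
  cfg <- tiny_model_config()
  members <- lapply(seq_len(n_members),
                    function(i) build_model(cfg, seed = seed + i))
  structure(list(members = members, stats = norm_stats(0, 1),
                 anchor = c(0L, 0L), input_size = cfg$input_size,
                 fold = integer(0),
                 val_metrics = matrix(0, n_members, 4,
                                      dimnames = list(NULL,
                                        c("precision", "recall", "f1",
                                          "predicted_singles"))),
                 loss = list(), model_config = cfg,
                 train_config = NULL),
            class = "hit_ensemble")
}

test_that("ensemble probability is the mean over members and mirror variants", {
  ens <- make_toy_ensemble(3)
  set.seed(4)
  patches <- array(rnorm(5 * 8 * 8), c(5, 8, 8))
  p_each <- sapply(ens$members, function(m)
    spihits:::predict_patches(list(m), patches, tta_mirror = FALSE))
  p_ens <- spihits:::predict_patches(ens$members, patches, tta_mirror = FALSE)
  expect_equal(p_ens, rowMeans(p_each), tolerance = 1e-12)
  # invariant to member order
  p_rev <- spihits:::predict_patches(rev(ens$members), patches,
                                     tta_mirror = FALSE)
  expect_equal(p_ens, p_rev, tolerance = 1e-12)
  # averaging duplicated copies of one model changes nothing
  m1 <- ens$members[[1]]
  p_dup <- spihits:::predict_patches(list(m1, m1, m1), patches,
                                     tta_mirror = FALSE)
  expect_equal(p_dup, p_each[, 1], tolerance = 1e-12)
  expect_true(all(p_ens >= 0 & p_ens <= 1))
})

test_that("mirror TTA averages four variants and fixes symmetric inputs", {
  ens <- make_toy_ensemble(1)
  m <- ens$members[[1]]
  set.seed(6)
  base <- matrix(rnorm(16), 4, 4)
  sym <- base + base[4:1, ] + base[, 4:1] + base[4:1, 4:1]  # mirror symmetric
  patches <- array(0, c(1, 8, 8))
  patches[1, , ] <- rbind(cbind(sym, sym[, 4:1]),
                          cbind(sym[4:1, ], sym[4:1, 4:1]))
  with_tta <- spihits:::predict_patches(list(m), patches, tta_mirror = TRUE)
  without <- spihits:::predict_patches(list(m), patches, tta_mirror = FALSE)
  expect_equal(with_tta, without, tolerance = 1e-10)
  # for an asymmetric input, TTA equals the explicit 4-variant average
  set.seed(7)
  pat <- array(rnorm(64), c(1, 8, 8))
  x <- pat[1, , ]
  variants <- list(x, x[8:1, ], x[, 8:1], x[8:1, 8:1])
  manual <- mean(vapply(variants, function(v) {
    pv <- array(0, c(1, 8, 8)); pv[1, , ] <- v
    spihits:::predict_patches(list(m), pv, tta_mirror = FALSE)
  }, numeric(1)))
  expect_equal(spihits:::predict_patches(list(m), pat, tta_mirror = TRUE),
               manual, tolerance = 1e-12)
})

test_that("predict() on patterns produces labeled probabilities and selections", {
  g <- mini_geometry(8L)
  ens <- make_toy_ensemble(2)
  set.seed(11)
  pats <- lapply(1:6, function(i)
    diffraction_pattern(matrix(rpois(64, 3), 8, 8), id = sprintf("f%02d", i)))
  res <- predict(ens, pats, geometry = g)
  expect_named(res, c("id", "probability", "label"))
  expect_equal(res$id, sprintf("f%02d", 1:6))
  expect_true(all(res$probability >= 0 & res$probability <= 1))
  expect_equal(res$label, as.integer(res$probability > 0.5))
  # strict threshold: probability exactly at the threshold is non-single
  expect_equal(as.integer(res$probability > res$probability[1])[1], 0L)
  sel <- predict(ens, pats, geometry = g, type = "selection", name = "cnn")
  expect_s3_class(sel, "selection")
  expect_setequal(sel$ids, res$id[res$label == 1L])
  # degenerate ensemble of one equals the single-model path
  ens1 <- make_toy_ensemble(1)
  prep <- spihits:::extract_patches(list(patterns = pats, geometry = g),
                                    ens1$input_size, ens1$anchor,
                                    stats = ens1$stats)
  expect_equal(ensemble_predict(ens1, pats, g, tta_mirror = FALSE)$probability,
               predict_single_model(ens1$members[[1]], prep$patches),
               tolerance = 1e-12)
})

test_that("selections and predictions round-trip through JSON/CSV", {
  sel <- selection("maxf1", sprintf("id%04d", c(3, 1, 8)))
  f <- tempfile(fileext = ".json")
  write_selection_json(sel, f)
  back <- read_selection_json(f)
  expect_equal(back$name, sel$name)
  expect_setequal(back$ids, sel$ids)
  preds <- data.frame(id = c("a", "b"), probability = c(0.9, 0.1),
                      label = c(1L, 0L))
  fc <- tempfile(fileext = ".csv")
  write_predictions_csv(preds, fc)
  expect_equal(utils::read.csv(fc), preds)
})
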