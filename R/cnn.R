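#' Residual classifier architecture configuration
#'
#' Describes the pre-activation residual network: patches enter an initial
#' 3x3 convolution with `base_filters` filters, pass through `n_blocks`
#' pre-activation residual blocks (two 3x3 convolutions each, identity
#' shortcut, 1x1 strided projection where shape or channels change),
#' downsampling by strided convolution with the filter count doubling at each
#' downsampling up to `max_filters`, and finish with batch norm, leaky ReLU,
#' global average pooling and a linear layer producing two class scores.
#'
#' The default plan downsamples 5 times on the long axis and 4 on the short
#' axis (one anisotropic (2, 1) stride), taking a 192 x 96 patch to the
#' 6 x 6 final feature map with channel sequence 16-32-64-128-256.
#'
#' @param input_size Patch size `(rows, cols)`; default `c(192, 96)`.
#' @param base_filters Filters of the initial convolution (default 16).
#' @param max_filters Filter cap (default 256).
#' @param n_blocks Number of residual blocks (default 8).
#' @param leaky_slope Negative slope of the leaky ReLU (default 0.01).
#' @param downsample_plan List of per-block `(row, col)` strides. Default:
#'   `(2,2)` at blocks 1, 3, 5, 7 and `(2,1)` at block 8.
#' @param final_size Expected final feature-map size; the plan is validated
#'   against it at build time.
#' @return Object of class `model_config`.
#' @export
model_config <- function(input_size = c(192L, 96L),
                         base_filters = 16L,
                         max_filters = 256L,
                         n_blocks = 8L,
                         leaky_slope = 0.01,
                         downsample_plan = NULL,
                         final_size = c(6L, 6L)) {
  input_size <- as.integer(input_size)
  if (is.null(downsample_plan)) {
    downsample_plan <- rep(list(c(1L, 1L)), n_blocks)
    for (i in seq_len(n_blocks))
      if (i %% 2 == 1) downsample_plan[[i]] <- c(2L, 2L)
    if (n_blocks >= 8) downsample_plan[[8]] <- c(2L, 1L)
  }
  if (length(downsample_plan) != n_blocks)
    stop("downsample_plan must give one stride pair per block")
  stopifnot(base_filters >= 1, max_filters >= base_filters,
            leaky_slope > 0, leaky_slope < 1)
  structure(list(input_size = input_size,
                 base_filters = as.integer(base_filters),
                 max_filters = as.integer(max_filters),
                 n_blocks = as.integer(n_blocks),
                 leaky_slope = leaky_slope,
                 downsample_plan = lapply(downsample_plan, as.integer),
                 final_size = as.integer(final_size)),
            class = "model_config")
}

#' Reduced architecture for CPU-scale runs
#'
#' A small instance of the same architecture family (32 x 16 patches, four
#' residual blocks, 8-32 filters, 4 x 4 final map) used by the package's
#' scaled demonstrations and tests.
#'
#' @return A `model_config`.
#' @export
model_config_small <- function() {
  model_config(input_size = c(32L, 16L), base_filters = 8L, max_filters = 32L,
               n_blocks = 4L,
               downsample_plan = list(c(2L, 2L), c(1L, 1L), c(2L, 2L),
                                      c(2L, 1L)),
               final_size = c(4L, 4L))
}

#' Augmentation configuration
#'
#' Magnitudes and per-op application probabilities for the on-the-fly
#' training augmentation: random rotation, scaling, elastic deformation,
#' gamma, additive Gaussian noise, Gaussian blur, mirroring, random shift and
#' cutout. Rotation, scaling, shift and elastic deformation are composed into
#' a single displacement field and applied with one bilinear interpolation.
#' Zero magnitudes yield the identity.
#'
#' @param p_geom Probability of applying the geometric warp.
#' @param rotation_deg Max |rotation| in degrees.
#' @param scale_range Scaling factor interval.
#' @param shift_px Max |shift| per axis in pixels.
#' @param p_elastic Probability that the warp includes an elastic field.
#' @param elastic_alpha,elastic_sigma Elastic displacement magnitude (px) and
#'   Gaussian smoothing of the random field (px).
#' @param p_gamma,gamma_range Gamma augmentation (applied on the min-max
#'   rescaled patch, preserving the original range).
#' @param p_noise,noise_sigma Additive Gaussian noise, post-normalization
#'   units.
#' @param p_blur,blur_sigma Gaussian blur sigma interval (px).
#' @param p_mirror Per-axis mirroring probability.
#' @param p_cutout,cutout_size,cutout_fill One square cutout box.
#' @return Object of class `augment_config`.
#' @export
augment_config <- function(p_geom = 0.3, rotation_deg = 15,
                           scale_range = c(0.85, 1.15), shift_px = 10,
                           p_elastic = 0.2, elastic_alpha = 100,
                           elastic_sigma = 10,
                           p_gamma = 0.3, gamma_range = c(0.7, 1.5),
                           p_noise = 0.15, noise_sigma = 0.1,
                           p_blur = 0.2, blur_sigma = c(0.5, 1.5),
                           p_mirror = 0.5,
                           p_cutout = 0.25, cutout_size = 32L,
                           cutout_fill = 0) {
  stopifnot(scale_range[1] <= scale_range[2], gamma_range[1] <= gamma_range[2],
            blur_sigma[1] <= blur_sigma[2], rotation_deg >= 0, shift_px >= 0,
            elastic_alpha >= 0, noise_sigma >= 0, cutout_size >= 1)
  structure(as.list(environment()), class = "augment_config")
}

#' Augmentation defaults for small patches
#'
#' The same pipeline with magnitudes scaled to 32 x 16 patches: gentler
#' geometry, no elastic/gamma component, sub-pixel-scale blur and a small
#' cutout box, so the few-pixel fringe structure the classifier relies on
#' survives augmentation.
#' @return An `augment_config`.
#' @export
augment_config_small <- function() {
  augment_config(p_geom = 0.3, rotation_deg = 10, scale_range = c(0.9, 1.1),
                 shift_px = 1, p_elastic = 0, p_gamma = 0,
                 p_noise = 0.15, noise_sigma = 0.05,
                 p_blur = 0.15, blur_sigma = c(0.3, 0.7),
                 p_mirror = 0.5, p_cutout = 0.15, cutout_size = 4L)
}

#' Training configuration
#'
#' Hyper-parameters of one training run under class imbalance: Adam with
#' initial learning rate `lr0` decayed by the polynomial schedule, minibatches
#' drawn with replacement with the single-hit class over-sampled to
#' `p_single_in_batch`, class-weighted cross entropy, and stratified
#' `n_folds`-fold cross validation.
#'
#' The defaults are the F1-optimizing configuration ("MaxF1": 2% singles per
#' batch, equal class weights). [train_config_moresh()] returns the
#' recall-leaning variant (5% singles, weights 0.1/0.9 for non-single/single).
#'
#' @param lr0 Initial learning rate.
#' @param batch_size Minibatch size.
#' @param iterations_per_epoch Iterations per epoch (epoch = bookkeeping unit).
#' @param epochs Number of epochs; total iterations =
#'   `epochs * iterations_per_epoch`.
#' @param p_single_in_batch Expected fraction of single hits per batch.
#' @param class_loss_weights Length-2 weights `(non-single, single)` of the
#'   cross-entropy loss.
#' @param n_folds Cross-validation folds.
#' @param power Exponent of the polynomial learning-rate schedule.
#' @param seed Integer seed for fold assignment, initialization, sampling and
#'   augmentation.
#' @param augment An `augment_config`, or `NULL` to disable augmentation.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-4, batch_size = 64L,
                         iterations_per_epoch = 50L, epochs = 1000L,
                         p_single_in_batch = 0.02,
                         class_loss_weights = c(0.5, 0.5),
                         n_folds = 5L, power = 0.9, seed = 1L,
                         augment = augment_config()) {
  if (p_single_in_batch <= 0 || p_single_in_batch >= 1)
    stop("p_single_in_batch must lie strictly between 0 and 1")
  if (any(class_loss_weights <= 0)) stop("class weights must be positive")
  stopifnot(lr0 > 0, batch_size >= 1, epochs >= 1, iterations_per_epoch >= 1,
            n_folds >= 2, power > 0)
  structure(list(lr0 = lr0, batch_size = as.integer(batch_size),
                 iterations_per_epoch = as.integer(iterations_per_epoch),
                 epochs = as.integer(epochs),
                 p_single_in_batch = p_single_in_batch,
                 class_loss_weights = as.numeric(class_loss_weights),
                 n_folds = as.integer(n_folds), power = power,
                 seed = as.integer(seed), augment = augment),
            class = "train_config")
}

#' @rdname train_config
#' @param ... Overrides passed on to [train_config()].
#' @export
train_config_moresh <- function(...) {
  args <- list(...)
  defaults <- list(p_single_in_batch = 0.05,
                   class_loss_weights = c(0.1, 0.9))
  do.call(train_config, utils::modifyList(defaults, args))
}

#' @rdname train_config
#' @param variant `"maxf1"` or `"moresh"`.
#' @details `train_config_small()` is the CPU-scale demonstration setting
#'   used with [model_config_small()]: 2 000 iterations per fold (40 epochs
#'   of 50), batch 32, initial learning rate 7e-4 (the schedule is 25x
#'   shorter than the full-scale run, so the rate is raised accordingly) and
#'   mirror-only augmentation - inference averages predictions over mirrored
#'   copies, which presumes mirror-consistent models, while the remaining
#'   augmentation ops are regularization this budget has no iterations to
#'   absorb. [augment_config_small()] is available for longer small-patch
#'   runs. The class-balance settings follow the chosen `variant`.
#' @export
train_config_small <- function(variant = c("maxf1", "moresh"), ...) {
  variant <- match.arg(variant)
  mirror_only <- augment_config(p_geom = 0, p_elastic = 0, p_gamma = 0,
                                p_noise = 0, p_blur = 0, p_mirror = 0.5,
                                p_cutout = 0)
  base <- list(lr0 = 7e-4, batch_size = 32L, epochs = 40L,
               iterations_per_epoch = 50L, augment = mirror_only)
  if (variant == "moresh")
    base <- c(base, list(p_single_in_batch = 0.05,
                         class_loss_weights = c(0.1, 0.9)))
  do.call(train_config, utils::modifyList(base, list(...)))
}

#' Build an untrained classifier
#'
#' Instantiates the residual network described by a `model_config`
#' (He-initialized weights, unit batch-norm scales). The per-block plan is
#' validated: the downsampling product must reproduce the configured final
#' feature-map size.
#'
#' @param config A `model_config`.
#' @param seed Optional seed for weight initialization.
#' @return Object of class `hit_cnn` with elements `config`, `layers`,
#'   `params`, `bn_state`.
#' @export
build_model <- function(config = model_config(), seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  layers <- model_layers(config)  # errors if the plan mismatches final_size
  structure(list(config = config, layers = layers,
                 params = init_params(layers),
                 bn_state = init_bn_state(layers)),
            class = "hit_cnn")
}

#' @export
print.hit_cnn <- function(x, ...) {
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<hit_cnn> %dx%d input, %d residual blocks, %s parameters\n",
              x$config$input_size[1], x$config$input_size[2],
              x$config$n_blocks, format(npar, big.mark = ",")))
  invisible(x)
}

#' Polynomial learning-rate schedule
#'
#' `lr(t) = lr0 * (1 - t/total)^power`: starts exactly at `lr0`, decays
#' monotonically and reaches 0 at `t = total`.
#'
#' @param iteration Iteration index, `0 <= iteration <= total`.
#' @param total Total iterations.
#' @param lr0 Initial learning rate.
#' @param power Schedule exponent (default 0.9).
#' @return Learning rate.
#' @export
lr_schedule <- function(iteration, total = 50000, lr0 = 1e-4, power = 0.9) {
  if (any(iteration < 0) || any(iteration > total))
    stop("iteration must lie in [0, total]")
  lr0 * (1 - iteration / total)^power
}

#' Imbalance-aware minibatch sampling
#'
#' Each batch slot independently draws the single-hit class with probability
#' `p_single`, then a uniformly random member of that class, with
#' replacement.
#'
#' @param labels Binary label vector of the training pool.
#' @param p_single Probability of drawing the single-hit class.
#' @param batch_size Slots per batch.
#' @return Integer vector of `batch_size` indices into `labels`.
#' @export
sample_minibatch <- function(labels, p_single, batch_size = 64L) {
  stopifnot(p_single >= 0, p_single <= 1)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (p_single > 0 && length(pos) == 0)
    stop("single-hit class requested but the pool holds no single hits")
  if (p_single < 1 && length(neg) == 0)
    stop("non-single class requested but the pool holds no non-single hits")
  take_pos <- stats::runif(batch_size) < p_single
  idx <- integer(batch_size)
  if (any(take_pos))
    idx[take_pos] <- pos[sample.int(length(pos), sum(take_pos), replace = TRUE)]
  if (any(!take_pos))
    idx[!take_pos] <- neg[sample.int(length(neg), sum(!take_pos),
                                     replace = TRUE)]
  idx
}

# separable Gaussian blur via the conv kernel (single channel)
gauss_blur <- function(patch, sigma) {
  if (sigma <= 0) return(patch)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  x <- array(patch, c(nrow(patch), ncol(patch), 1L, 1L))
  kv <- array(k, c(2L * r + 1L, 1L, 1L, 1L))
  x <- conv2d(x, kv, 0, stride = c(1L, 1L), pad = c(r, 0L))
  kh <- array(k, c(1L, 2L * r + 1L, 1L, 1L))
  x <- conv2d(x, kh, 0, stride = c(1L, 1L), pad = c(0L, r))
  matrix(x, nrow(patch), ncol(patch))
}

#' Augment a patch
#'
#' Applies the training-time augmentation pipeline to one patch, in
#' standardized intensity units. Geometric operations (rotation about the
#' patch center, isotropic scaling, shift, elastic deformation) are composed
#' into a single displacement field and resolved with one bilinear
#' interpolation; photometric operations (gamma, Gaussian noise, Gaussian
#' blur), mirroring and cutout follow. The class label is untouched by
#' construction.
#'
#' Uses the current R random stream; seed with `set.seed()` to reproduce.
#'
#' @param patch Numeric matrix.
#' @param config An `augment_config`.
#' @return Augmented patch, same shape.
#' @export
augment <- function(patch, config = augment_config()) {
  stopifnot(is.matrix(patch), inherits(config, "augment_config"))
  H <- nrow(patch); W <- ncol(patch)
  if (stats::runif(1) < config$p_geom) {
    ang <- stats::runif(1, -config$rotation_deg, config$rotation_deg) * pi / 180
    sc <- stats::runif(1, config$scale_range[1], config$scale_range[2])
    sh <- stats::runif(2, -config$shift_px, config$shift_px)
    cr <- (H - 1) / 2; cc <- (W - 1) / 2
    R <- matrix(rep(0:(H - 1), W), H, W) - cr
    C <- matrix(rep(0:(W - 1), each = H), H, W) - cc
    # inverse map: source = center + R^-1 (target - shift) / scale
    mr <- cr + (cos(ang) * (R - sh[1]) + sin(ang) * (C - sh[2])) / sc
    mc <- cc + (-sin(ang) * (R - sh[1]) + cos(ang) * (C - sh[2])) / sc
    if (config$elastic_alpha > 0 && stats::runif(1) < config$p_elastic) {
      dr <- gauss_blur(matrix(stats::rnorm(H * W), H, W), config$elastic_sigma)
      dc <- gauss_blur(matrix(stats::rnorm(H * W), H, W), config$elastic_sigma)
      nrm <- max(sqrt(dr^2 + dc^2))
      if (nrm > 0) {
        dr <- dr / nrm * config$elastic_alpha / max(H, W) * 2
        dc <- dc / nrm * config$elastic_alpha / max(H, W) * 2
      }
      mr <- mr + dr; mc <- mc + dc
    }
    patch <- .warp_bilinear(patch, mr, mc, 0)
  }
  if (stats::runif(1) < config$p_gamma) {
    g <- stats::runif(1, config$gamma_range[1], config$gamma_range[2])
    rng <- range(patch)
    if (diff(rng) > 0) {
      z <- (patch - rng[1]) / diff(rng)
      patch <- rng[1] + diff(rng) * z^g
    }
  }
  if (stats::runif(1) < config$p_noise && config$noise_sigma > 0)
    patch <- patch + matrix(stats::rnorm(H * W, sd = config$noise_sigma), H, W)
  if (stats::runif(1) < config$p_blur) {
    s <- stats::runif(1, config$blur_sigma[1], config$blur_sigma[2])
    patch <- gauss_blur(patch, s)
  }
  if (stats::runif(1) < config$p_mirror) patch <- patch[H:1, , drop = FALSE]
  if (stats::runif(1) < config$p_mirror) patch <- patch[, W:1, drop = FALSE]
  if (stats::runif(1) < config$p_cutout) {
    s <- min(config$cutout_size, H, W)
    r0 <- sample.int(H - s + 1L, 1L); c0 <- sample.int(W - s + 1L, 1L)
    patch[r0:(r0 + s - 1L), c0:(c0 + s - 1L)] <- config$cutout_fill
  }
  patch
}

#' Train a single classifier on one fold
#'
#' Runs the configured iteration budget of Adam on class-weighted cross
#' entropy, drawing imbalance-corrected minibatches with on-the-fly
#' augmentation and decaying the learning rate with the polynomial schedule.
#'
#' @param patches 3-d array `(n, rows, cols)` of standardized patches.
#' @param labels Binary labels, length `n`.
#' @param train A `train_config` (its seed is NOT applied here; seed the
#'   stream yourself or use [hit_classifier()]).
#' @param model_cfg A `model_config` matching the patch size.
#' @param verbose Print an epoch summary line every `verbose` epochs (0 = off).
#' @return List: `model` (a `hit_cnn`), `loss` (per-epoch mean training
#'   loss).
#' @export
train_fold <- function(patches, labels, train = train_config(),
                       model_cfg = model_config(), verbose = 0) {
  stopifnot(length(dim(patches)) == 3L, dim(patches)[1] == length(labels))
  if (!all(sort(unique(labels)) %in% c(0L, 1L)))
    stop("labels must be binary")
  hw <- dim(patches)[2:3]
  if (!all(hw == model_cfg$input_size))
    stop("patch size does not match the model input size")
  model <- build_model(model_cfg)
  opt <- adam_init(model$params)
  total <- train$epochs * train$iterations_per_epoch
  losses <- numeric(train$epochs)
  it <- 0L
  for (ep in seq_len(train$epochs)) {
    lr <- lr_schedule(it, total, train$lr0, train$power)
    ep_loss <- 0
    for (k in seq_len(train$iterations_per_epoch)) {
      idx <- sample_minibatch(labels, train$p_single_in_batch,
                              train$batch_size)
      xb <- array(0, c(hw[1], hw[2], 1L, train$batch_size))
      for (m in seq_along(idx)) {
        pm <- patches[idx[m], , , drop = TRUE]
        if (!is.null(train$augment)) pm <- augment(pm, train$augment)
        xb[, , 1L, m] <- pm
      }
      fw <- net_forward(model, xb, train = TRUE)
      model$bn_state <- fw$bn_state
      ce <- weighted_ce(fw$logits, labels[idx], train$class_loss_weights)
      if (!is.finite(ce$loss))
        stop(sprintf("training diverged (non-finite loss at iteration %d)",
                     it + 1L))
      grads <- net_backward(model, fw$caches, ce$dlogits)
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + ce$loss
      it <- it + 1L
    }
    losses[ep] <- ep_loss / train$iterations_per_epoch
    if (verbose > 0 && ep %% verbose == 0)
      message(sprintf("epoch %d/%d  lr %.2e  loss %.4f",
                      ep, train$epochs, lr, losses[ep]))
  }
  list(model = model, loss = losses)
}

# Stratified fold assignment: seeded shuffle within each class, folds filled
# cyclically so per-fold class proportions match the pool.
stratified_folds <- function(labels, n_folds) {
  for (cls in c(0L, 1L))
    if (sum(labels == cls) < n_folds)
      stop(sprintf("class %d has fewer members (%d) than folds (%d)",
                   cls, sum(labels == cls), n_folds))
  fold <- integer(length(labels))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Extract standardized CNN patches from a dataset
#'
#' Crops every frame at the given anchor and standardizes with `stats`
#' (computing the statistics from the crops themselves, masked pixels
#' excluded, when `stats` is `NULL`).
#'
#' @param dataset A `labeled_dataset` (or list of patterns with a geometry).
#' @param size Patch size `(rows, cols)`.
#' @param anchor Crop anchor; default the live-panel region nearest the beam
#'   center.
#' @param stats A `norm_stats`, or `NULL` to compute from these crops.
#' @return List: `patches` array `(n, rows, cols)`, `stats`, `anchor`,
#'   `size`.
#' @export
extract_patches <- function(dataset, size, anchor = NULL, stats = NULL) {
  geometry <- dataset$geometry
  patterns <- dataset$patterns
  if (is.null(anchor)) anchor <- default_crop_anchor(geometry, size)
  n <- length(patterns)
  raw <- array(0, c(n, size[1], size[2]))
  for (i in seq_len(n))
    raw[i, , ] <- crop_patch(patterns[[i]], anchor, size)
  if (is.null(stats)) {
    rows <- (anchor[1] + 1L):(anchor[1] + size[1])
    cols <- (anchor[2] + 1L):(anchor[2] + size[2])
    stats <- compute_norm_stats(raw, geometry$panel_mask[rows, cols])
  }
  patches <- (raw - stats$mu) / stats$sigma
  list(patches = patches, stats = stats, anchor = as.integer(anchor),
       size = as.integer(size))
}

#' Fit the single-hit classifier ensemble
#'
#' The package's main fitting function. Crops and standardizes the training
#' frames, assigns seeded stratified folds, trains one residual classifier
#' per fold on the remaining folds (class-rebalanced sampling, weighted cross
#' entropy, on-the-fly augmentation, polynomial learning-rate decay), and
#' evaluates each on its held-out fold. The five (in general `n_folds`)
#' models plus the shared normalization statistics form the inference
#' ensemble.
#'
#' @param dataset A `labeled_dataset` (frames + binary labels).
#' @param model A `model_config`.
#' @param train A `train_config`; its `seed` drives folds, initialization,
#'   sampling and augmentation.
#' @param anchor Optional crop anchor (default: live-panel region nearest the
#'   beam center).
#' @param verbose Epoch-print period per fold (0 = silent).
#' @return Object of class `hit_ensemble`: members, normalization stats, fold
#'   assignment, per-fold validation metrics, loss traces, configs.
#' @export
#' @seealso [predict.hit_ensemble()], [summary.hit_ensemble()]
hit_classifier <- function(dataset, model = model_config(),
                           train = train_config(), anchor = NULL,
                           verbose = 0) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(model, "model_config"),
            inherits(train, "train_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(train$seed)
  prep <- extract_patches(dataset, model$input_size, anchor)
  labels <- as.integer(dataset$labels)
  fold <- stratified_folds(labels, train$n_folds)
  members <- vector("list", train$n_folds)
  losses <- vector("list", train$n_folds)
  val <- matrix(NA_real_, train$n_folds, 4,
                dimnames = list(NULL, c("precision", "recall", "f1",
                                        "predicted_singles")))
  for (f in seq_len(train$n_folds)) {
    tr_idx <- which(fold != f)
    fit <- train_fold(prep$patches[tr_idx, , , drop = FALSE], labels[tr_idx],
                      train, model, verbose = verbose)
    members[[f]] <- fit$model
    losses[[f]] <- fit$loss
    va_idx <- which(fold == f)
    pr <- predict_patches(list(fit$model), prep$patches[va_idx, , ,
                                                        drop = FALSE],
                          tta_mirror = FALSE)
    pred <- as.integer(pr > 0.5)
    met <- precision_recall_f1(confusion_counts(labels[va_idx], pred))
    val[f, ] <- c(met, sum(pred))
  }
  structure(list(members = members, stats = prep$stats,
                 anchor = prep$anchor, input_size = model$input_size,
                 fold = fold, val_metrics = val, loss = losses,
                 model_config = model, train_config = train),
            class = "hit_ensemble")
}
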