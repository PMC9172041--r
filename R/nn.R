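# Internal neural-network machinery for the residual classifier.
#
# Tensors are column-major R arrays dim (H, W, C, B). Convolutions run
# through the C++ im2col/BLAS kernels; batch normalization, activations,
# pooling and the classification head are vectorized R. All parameters live
# in a flat named list so the Adam update is a simple mapply over leaves.

conv2d <- function(x, w, b, stride = c(1L, 1L), pad = c(1L, 1L),
                   keep_cols = FALSE) {
  .conv2d_forward(x, w, b, as.integer(stride), as.integer(pad), keep_cols)
}

conv2d_grad <- function(x, w, dy, stride = c(1L, 1L), pad = c(1L, 1L),
                        cols = NULL) {
  .conv2d_backward(x, w, dy, as.integer(stride), as.integer(pad), cols)
}

lrelu <- function(x, slope) .lrelu(x, slope)
lrelu_grad <- function(x, dy, slope) .lrelu_grad(x, dy, slope)

# ---- batch normalization over (H, W, B) per channel --------------------

bn_forward <- function(x, gamma, beta, run_mean, run_var, train,
                       momentum = 0.1, eps = 1e-5) {
  if (train) {
    st <- .bn_stats(x)
    mu <- st$mean; v <- st$var
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
  }
  sd_ <- sqrt(v + eps)
  xhat <- .channel_affine(x, 1 / sd_, -mu / sd_)
  y <- .channel_affine(xhat, gamma, beta)
  list(y = y, xhat = xhat, sd = sd_,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dy, cache, gamma) {
  .bn_backward(dy, cache$xhat, gamma, cache$sd)
}

# ---- architecture ------------------------------------------------------

# Layer plan implied by a model_config: initial conv, n pre-activation
# residual blocks (filters doubling at each downsampling, capped), then
# BN -> LReLU -> global average pooling -> linear head with 2 logits.
model_layers <- function(config) {
  layers <- list()
  cur <- config$base_filters
  layers$conv_in <- list(type = "conv", cin = 1L, cout = cur)
  size <- config$input_size
  for (i in seq_len(config$n_blocks)) {
    s <- config$downsample_plan[[i]]
    cin <- cur
    if (any(s > 1L)) cur <- min(2L * cur, config$max_filters)
    if (any((size %% s) != 0))
      stop("downsample plan does not divide the spatial size evenly")
    size <- size %/% s
    layers[[sprintf("block%d", i)]] <-
      list(type = "block", cin = cin, cout = cur, stride = as.integer(s),
           proj = (cin != cur) || any(s > 1L))
  }
  if (!all(size == config$final_size))
    stop(sprintf("downsample plan yields a %dx%d final map, expected %dx%d",
                 size[1], size[2], config$final_size[1], config$final_size[2]))
  layers$head <- list(type = "head", cin = cur)
  layers
}

he_w <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

init_params <- function(layers) {
  p <- list()
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (l$type == "conv") {
      p[[paste0(nm, ".w")]] <- he_w(3L, 3L, l$cin, l$cout)
      p[[paste0(nm, ".b")]] <- numeric(l$cout)
    } else if (l$type == "block") {
      p[[paste0(nm, ".bn1.gamma")]] <- rep(1, l$cin)
      p[[paste0(nm, ".bn1.beta")]] <- numeric(l$cin)
      p[[paste0(nm, ".conv1.w")]] <- he_w(3L, 3L, l$cin, l$cout)
      p[[paste0(nm, ".conv1.b")]] <- numeric(l$cout)
      p[[paste0(nm, ".bn2.gamma")]] <- rep(1, l$cout)
      p[[paste0(nm, ".bn2.beta")]] <- numeric(l$cout)
      p[[paste0(nm, ".conv2.w")]] <- he_w(3L, 3L, l$cout, l$cout)
      p[[paste0(nm, ".conv2.b")]] <- numeric(l$cout)
      if (l$proj) {
        p[[paste0(nm, ".proj.w")]] <- he_w(1L, 1L, l$cin, l$cout)
        p[[paste0(nm, ".proj.b")]] <- numeric(l$cout)
      }
    } else {  # head
      p[[paste0(nm, ".bn.gamma")]] <- rep(1, l$cin)
      p[[paste0(nm, ".bn.beta")]] <- numeric(l$cin)
      p[[paste0(nm, ".dense.w")]] <- matrix(stats::rnorm(l$cin * 2,
                                                         sd = sqrt(1 / l$cin)),
                                            l$cin, 2)
      p[[paste0(nm, ".dense.b")]] <- numeric(2)
    }
  }
  p
}

init_bn_state <- function(layers) {
  s <- list()
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (l$type == "block") {
      s[[paste0(nm, ".bn1")]] <- list(mean = numeric(l$cin), var = rep(1, l$cin))
      s[[paste0(nm, ".bn2")]] <- list(mean = numeric(l$cout), var = rep(1, l$cout))
    } else if (l$type == "head") {
      s[[paste0(nm, ".bn")]] <- list(mean = numeric(l$cin), var = rep(1, l$cin))
    }
  }
  s
}

# Forward pass. x: array (H, W, 1, B). Returns logits (2 x B) and, when
# `train`, the caches needed for the backward pass plus updated BN state.
net_forward <- function(model, x, train = FALSE) {
  layers <- model$layers; p <- model$params; st <- model$bn_state
  slope <- model$config$leaky_slope
  # during training each conv keeps its im2col matrix for backward reuse
  cf <- function(x, w, b, stride = c(1L, 1L), pad = c(1L, 1L)) {
    r <- conv2d(x, w, b, stride, pad, keep_cols = train)
    if (train) r else list(y = r, cols = NULL)
  }
  caches <- list()
  c0 <- cf(x, p$conv_in.w, p$conv_in.b)
  h <- c0$y
  caches$conv_in <- list(x = x, cols = c0$cols)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (l$type != "block") next
    bn1k <- paste0(nm, ".bn1"); bn2k <- paste0(nm, ".bn2")
    b1 <- bn_forward(h, p[[paste0(nm, ".bn1.gamma")]],
                     p[[paste0(nm, ".bn1.beta")]],
                     st[[bn1k]]$mean, st[[bn1k]]$var, train)
    if (train) st[[bn1k]] <- list(mean = b1$run_mean, var = b1$run_var)
    a1 <- lrelu(b1$y, slope)
    cc1 <- cf(a1, p[[paste0(nm, ".conv1.w")]],
              p[[paste0(nm, ".conv1.b")]], stride = l$stride)
    h1 <- cc1$y
    b2 <- bn_forward(h1, p[[paste0(nm, ".bn2.gamma")]],
                     p[[paste0(nm, ".bn2.beta")]],
                     st[[bn2k]]$mean, st[[bn2k]]$var, train)
    if (train) st[[bn2k]] <- list(mean = b2$run_mean, var = b2$run_var)
    a2 <- lrelu(b2$y, slope)
    cc2 <- cf(a2, p[[paste0(nm, ".conv2.w")]], p[[paste0(nm, ".conv2.b")]])
    h2 <- cc2$y
    ccp <- NULL
    sc <- if (l$proj) {
      ccp <- cf(a1, p[[paste0(nm, ".proj.w")]], p[[paste0(nm, ".proj.b")]],
                stride = l$stride, pad = c(0L, 0L))
      ccp$y
    } else h
    out <- h2 + sc
    caches[[nm]] <- list(x = h, b1 = b1, a1 = a1, h1 = h1, b2 = b2, a2 = a2,
                         cols1 = cc1$cols, cols2 = cc2$cols,
                         colsp = if (is.null(ccp)) NULL else ccp$cols)
    h <- out
  }
  hk <- "head.bn"
  bh <- bn_forward(h, p$head.bn.gamma, p$head.bn.beta,
                   st[[hk]]$mean, st[[hk]]$var, train)
  if (train) st[[hk]] <- list(mean = bh$run_mean, var = bh$run_var)
  ah <- lrelu(bh$y, slope)
  d <- dim(ah)
  feat <- matrix(colMeans(matrix(ah, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  logits <- crossprod(p$head.dense.w, feat) +
    matrix(p$head.dense.b, 2, d[4])
  caches$head <- list(x = h, bh = bh, ah = ah, feat = feat, dims = d)
  list(logits = logits, caches = caches, bn_state = st)
}

# Backward pass from dlogits (2 x B); returns gradient list keyed like params.
net_backward <- function(model, caches, dlogits) {
  layers <- model$layers; p <- model$params
  slope <- model$config$leaky_slope
  g <- list()
  hc <- caches$head; d <- hc$dims
  g$head.dense.w <- hc$feat %*% t(dlogits)
  g$head.dense.b <- rowSums(dlogits)
  dfeat <- p$head.dense.w %*% dlogits               # C x B
  dah <- array(rep(as.numeric(dfeat), each = d[1] * d[2]) / (d[1] * d[2]), d)
  dbh <- lrelu_grad(hc$bh$y, dah, slope)
  bb <- bn_backward(dbh, hc$bh, p$head.bn.gamma)
  g$head.bn.gamma <- bb$dgamma; g$head.bn.beta <- bb$dbeta
  dh <- bb$dx
  for (nm in rev(names(layers))) {
    l <- layers[[nm]]
    if (l$type != "block") next
    cc <- caches[[nm]]
    # conv2 branch
    cg2 <- conv2d_grad(cc$a2, p[[paste0(nm, ".conv2.w")]], dh,
                       cols = cc$cols2)
    g[[paste0(nm, ".conv2.w")]] <- cg2$dw
    g[[paste0(nm, ".conv2.b")]] <- cg2$db
    da2 <- cg2$dx
    db2y <- lrelu_grad(cc$b2$y, da2, slope)
    bb2 <- bn_backward(db2y, cc$b2, p[[paste0(nm, ".bn2.gamma")]])
    g[[paste0(nm, ".bn2.gamma")]] <- bb2$dgamma
    g[[paste0(nm, ".bn2.beta")]] <- bb2$dbeta
    cg1 <- conv2d_grad(cc$a1, p[[paste0(nm, ".conv1.w")]], bb2$dx,
                       stride = l$stride, cols = cc$cols1)
    g[[paste0(nm, ".conv1.w")]] <- cg1$dw
    g[[paste0(nm, ".conv1.b")]] <- cg1$db
    da1 <- cg1$dx
    dx_in <- NULL
    if (l$proj) {
      cgp <- conv2d_grad(cc$a1, p[[paste0(nm, ".proj.w")]], dh,
                         stride = l$stride, pad = c(0L, 0L),
                         cols = cc$colsp)
      g[[paste0(nm, ".proj.w")]] <- cgp$dw
      g[[paste0(nm, ".proj.b")]] <- cgp$db
      da1 <- da1 + cgp$dx
    } else {
      dx_in <- dh  # identity shortcut feeds straight through
    }
    db1y <- lrelu_grad(cc$b1$y, da1, slope)
    bb1 <- bn_backward(db1y, cc$b1, p[[paste0(nm, ".bn1.gamma")]])
    g[[paste0(nm, ".bn1.gamma")]] <- bb1$dgamma
    g[[paste0(nm, ".bn1.beta")]] <- bb1$dbeta
    dh <- if (is.null(dx_in)) bb1$dx else bb1$dx + dx_in
  }
  cgi <- conv2d_grad(caches$conv_in$x, p$conv_in.w, dh,
                     cols = caches$conv_in$cols)
  g$conv_in.w <- cgi$dw
  g$conv_in.b <- cgi$db
  g
}

# ---- loss --------------------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Class-weighted cross entropy. labels in {0,1}; weights = c(w_nonsingle,
# w_single). Returns the mean weighted loss and dlogits for the backward
# pass.
weighted_ce <- function(logits, labels, weights) {
  B <- ncol(logits)
  probs <- softmax_cols(logits)
  idx <- labels + 1L
  w <- weights[idx]
  pick <- probs[cbind(idx, seq_len(B))]
  loss <- mean(-w * log(pmax(pick, 1e-12)))
  onehot <- matrix(0, 2, B)
  onehot[cbind(idx, seq_len(B))] <- 1
  dlogits <- sweep(probs - onehot, 2, w, "*") / B
  list(loss = loss, dlogits = dlogits, probs = probs)
}

# ---- Adam --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    gk <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}
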