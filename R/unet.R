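#' U-Net segmenter configuration
#'
#' The full-scale protocol uses 192 x 160 x 128 input patches at a working
#' spacing of 1 x 1 x 2 mm, five cross-validation folds, 250 epochs of
#' RMSProp at learning rate 1e-4 and a categorical Dice loss with equal
#' class weights. The `"small"` preset shrinks the patch, depth, channel
#' widths and schedule to desk scale for CPU training on phantoms; every
#' field remains individually overridable.
#'
#' Architecture choices fixed here (conventional 3-D U-Net): `depth`
#' poolings, two 3x3x3 convolutions with instance normalization and ReLU
#' per level, nearest-neighbour upsampling with convolution, skip
#' concatenation, 1x1x1 classification head, no augmentation. Intensities
#' are clipped to `hu_window` and scaled to `[0, 1]`. Optionally three
#' normalized physical-coordinate channels are appended to the input
#' (`coord_features`), which lets patch-based training localize organs
#' that share an attenuation value.
#'
#' @param scale `"full"` or `"small"` preset.
#' @param patch input patch size (voxels); each dimension must be
#'   divisible by `2^depth`.
#' @param spacing working voxel spacing (mm).
#' @param folds number of cross-validation folds (>= 2).
#' @param epochs training epochs (>= 1).
#' @param steps_per_epoch gradient steps (random crops) per epoch.
#' @param lr RMSProp learning rate.
#' @param depth number of pooling levels.
#' @param base_channels channels at the first level (doubled per level).
#' @param n_classes number of classes (background + 3 organs).
#' @param normalization `"instance"`, `"batch"` or `"none"`. Instance
#'   normalization is the conventional choice at full scale. With very
#'   small windows (the `"small"` preset) per-window statistics of
#'   homogeneous windows degenerate; the preset keeps instance
#'   normalization but raises `norm_eps` so it is variance-floored.
#' @param norm_eps variance floor of the normalization. The default 1e-5
#'   is a pure numerical guard; the `"small"` preset uses 1e-1 so that
#'   windows of air or uniform tissue are not amplified to unit variance
#'   (the floor applies identically in training and inference).
#' @param ce_weight weight of an auxiliary cross-entropy term added to
#'   the training gradient. The full-scale preset trains on the
#'   categorical Dice loss alone; at desk scale single-crop Dice
#'   gradients are too sparse to escape the confident-background optimum
#'   and the preset mixes in cross-entropy with weight 1. Validation and
#'   model selection always use the Dice loss.
#' @param coord_features append normalized coordinate channels?
#' @param hu_window intensity clipping window (HU).
#' @param dice_eps smoothing epsilon of the Dice loss.
#' @param fg_crop_bias fraction of training crops centred on a random
#'   foreground voxel (class chosen uniformly among those present); the
#'   rest are uniform over valid origins. Foreground-centred sampling
#'   keeps the sparse organ classes represented in the Dice loss.
#' @param stride sliding-window stride for inference; default half patch.
#' @return A `unet_config` object.
#' @export
unet_config <- function(scale = c("full", "small"), patch = NULL,
                        spacing = NULL, folds = NULL, epochs = NULL,
                        steps_per_epoch = NULL, lr = NULL, depth = NULL,
                        base_channels = NULL, n_classes = 4L,
                        normalization = NULL, norm_eps = NULL,
                        ce_weight = NULL, coord_features = TRUE,
                        hu_window = c(-1024, 600), dice_eps = 1e-5,
                        fg_crop_bias = 0.5, stride = NULL) {
  scale <- match.arg(scale)
  preset <- if (scale == "full") {
    list(patch = c(192L, 160L, 128L), spacing = c(1, 1, 2), folds = 5L,
         epochs = 250L, steps_per_epoch = 32L, lr = 1e-4, depth = 4L,
         base_channels = 16L, stride = NULL, normalization = "instance",
         ce_weight = 0)
  } else {
    # desk-scale: 32 mm cubic patches, shallow net, non-overlapping
    # inference windows; trains on one CPU core in a few minutes
    # batch (running-statistics) normalization at this scale: per-window
    # statistics of small homogeneous inference windows degenerate, so
    # training uses per-crop statistics and inference frozen averages
    list(patch = c(16L, 16L, 16L), spacing = c(2, 2, 2), folds = 2L,
         epochs = 120L, steps_per_epoch = 20L, lr = 2e-2, depth = 2L,
         base_channels = 6L, stride = c(16L, 16L, 16L),
         normalization = "instance", norm_eps = 1e-1, ce_weight = 1)
  }
  cfg <- list(
    scale = scale,
    patch = as.integer(patch %||% preset$patch),
    spacing = check_spacing(spacing %||% preset$spacing),
    folds = as.integer(folds %||% preset$folds),
    epochs = as.integer(epochs %||% preset$epochs),
    steps_per_epoch = as.integer(steps_per_epoch %||% preset$steps_per_epoch),
    lr = lr %||% preset$lr,
    optimizer = "rmsprop",
    depth = as.integer(depth %||% preset$depth),
    base_channels = as.integer(base_channels %||% preset$base_channels),
    n_classes = as.integer(n_classes),
    normalization = match.arg(normalization %||% preset$normalization,
                              c("instance", "batch", "none")),
    norm_eps = norm_eps %||% preset$norm_eps %||% 1e-5,
    ce_weight = ce_weight %||% preset$ce_weight %||% 0,
    coord_features = isTRUE(coord_features),
    hu_window = hu_window, dice_eps = dice_eps,
    fg_crop_bias = fg_crop_bias, stride = stride %||% preset$stride)
  if (any(cfg$patch %% 2^cfg$depth != 0))
    stop("patch dimensions must be divisible by 2^depth = ", 2^cfg$depth)
  if (cfg$folds < 2) stop("need at least 2 folds")
  if (cfg$epochs < 1) stop("need at least 1 epoch")
  cfg$stride <- as.integer(cfg$stride %||% pmax(1L, cfg$patch %/% 2L))
  class(cfg) <- "unet_config"
  cfg
}

#' Categorical Dice loss
#'
#' `1 - mean_c (2 * sum(p_c g_c) + eps) / (sum(p_c) + sum(g_c) + eps)`
#' over the classes, with equal class weights. `eps` (default `1e-5`)
#' keeps absent classes well-defined. Bounded in `[0, 1]`.
#'
#' @param prob matrix of class probabilities (classes x voxels), columns
#'   summing to 1, or an equivalent 4-D array (classes first).
#' @param onehot one-hot ground truth of the same shape.
#' @param eps smoothing epsilon.
#' @return Scalar loss.
#' @export
dice_loss <- function(prob, onehot, eps = 1e-5) {
  prob <- as_class_matrix(prob)
  onehot <- as_class_matrix(onehot)
  if (!identical(dim(prob), dim(onehot)))
    stop("probability and one-hot shapes differ")
  num <- 2 * rowSums(prob * onehot) + eps
  den <- rowSums(prob) + rowSums(onehot) + eps
  1 - mean(num / den)
}

as_class_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (is.null(d)) stop("expected a classes-by-voxels matrix or array")
  matrix(x, nrow = d[1])
}

dice_loss_grad <- function(prob, onehot, eps = 1e-5) {
  C <- nrow(prob)
  I <- rowSums(prob * onehot)
  den <- rowSums(prob) + rowSums(onehot) + eps
  num <- 2 * I + eps
  # d/dp[c,v] of -(1/C) * num_c / den_c
  -(2 * onehot * den - num) / (C * den^2)
}

onehot_encode <- function(labels_vec, n_classes) {
  m <- matrix(0, n_classes, length(labels_vec))
  m[cbind(labels_vec + 1L, seq_along(labels_vec))] <- 1
  m
}

normalize_hu <- function(x, window) {
  v <- pmin(pmax(as.numeric(x), window[1]), window[2])
  (v - window[1]) / (window[2] - window[1])
}

# ---- network construction ---------------------------------------------

conv_layer <- function(cin, cout) {
  fan_in <- cin * 27
  list(W = matrix(rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in),
       b = numeric(cout), gamma = rep(1, cout), beta = numeric(cout),
       rm = numeric(cout), rv = rep(1, cout))  # running stats (batch norm)
}

#' @noRd
unet_init <- function(config, seed = 1L) {
  with_seed(seed, {
    in_ch <- 1L + if (config$coord_features) 3L else 0L
    D <- config$depth
    ch <- config$base_channels * 2^(0:D)
    enc <- list()
    prev <- in_ch
    for (l in 0:D) {
      enc[[l + 1]] <- list(a = conv_layer(prev, ch[l + 1]),
                           b = conv_layer(ch[l + 1], ch[l + 1]))
      prev <- ch[l + 1]
    }
    dec <- list()
    for (l in (D - 1):0) {
      dec[[D - l]] <- list(up = conv_layer(ch[l + 2], ch[l + 1]),
                           a = conv_layer(2 * ch[l + 1], ch[l + 1]),
                           b = conv_layer(ch[l + 1], ch[l + 1]))
    }
    C0 <- ch[1]
    # near-zero head: training starts from uniform class probabilities,
    # avoiding early saturation of the softmax
    head <- list(W = matrix(rnorm(config$n_classes * C0, 0, 0.01),
                            config$n_classes, C0),
                 b = numeric(config$n_classes))
    list(enc = enc, dec = dec, head = head, config = config)
  })
}

# ---- forward / backward ------------------------------------------------

# activation: leaky ReLU (slope 0.1) — keeps gradient flowing everywhere,
# which matters for the norm-free configuration where saturated units
# cannot recover
LEAK <- 0.1

conv_block_fwd <- function(layer, x, dims, norm = "instance",
                           training = TRUE, norm_eps = 1e-5) {
  if (training) {
    cv <- cpp_conv3_forward_col(x, layer$W, layer$b, dims)
    y1 <- cv$y
    col <- cv$col
  } else {
    y1 <- cpp_conv3_forward(x, layer$W, layer$b, dims)
    col <- NULL
  }
  if (norm == "none") {
    act <- ifelse(y1 > 0, 1, LEAK)
    return(list(out = y1 * act, layer = layer,
                cache = list(x = x, col = col, dims = dims, act = act,
                             norm = norm)))
  }
  if (norm == "batch" && !training) {
    # frozen running statistics: deterministic, content-independent
    inv_std <- 1 / sqrt(layer$rv + norm_eps)
    xhat <- (y1 - layer$rm) * inv_std
  } else {
    mu <- rowMeans(y1)
    v <- rowMeans(y1^2) - mu^2
    # norm_eps doubles as a variance floor: homogeneous windows (air,
    # uniform tissue) are not amplified to unit variance
    inv_std <- 1 / sqrt(v + norm_eps)
    xhat <- (y1 - mu) * inv_std
    if (norm == "batch" && training) {
      layer$rm <- 0.9 * layer$rm + 0.1 * mu
      layer$rv <- 0.9 * layer$rv + 0.1 * v
    }
  }
  y2 <- layer$gamma * xhat + layer$beta
  act <- ifelse(y2 > 0, 1, LEAK)
  list(out = y2 * act, layer = layer,
       cache = list(x = x, col = col, dims = dims, xhat = xhat,
                    inv_std = inv_std, act = act, norm = norm))
}

conv_bwd_dispatch <- function(cache, W, dy1) {
  if (is.null(cache$col)) {
    cpp_conv3_backward(cache$x, W, dy1, cache$dims)
  } else {
    cpp_conv3_backward_col(cache$col, W, dy1, cache$dims, nrow(cache$x))
  }
}

conv_block_bwd <- function(layer, cache, dout) {
  if (cache$norm %in% c("instance", "batch")) {
    dy2 <- dout * cache$act
    dgamma <- rowSums(dy2 * cache$xhat)
    dbeta <- rowSums(dy2)
    dxhat <- dy2 * layer$gamma
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * cache$xhat)
    dy1 <- cache$inv_std * (dxhat - m1 - cache$xhat * m2)
    g <- conv_bwd_dispatch(cache, layer$W, dy1)
    list(dx = g$dx,
         grads = list(W = g$dW, b = as.numeric(g$db), gamma = dgamma,
                      beta = dbeta))
  } else {
    dy1 <- dout * cache$act
    g <- conv_bwd_dispatch(cache, layer$W, dy1)
    list(dx = g$dx,
         grads = list(W = g$dW, b = as.numeric(g$db),
                      gamma = layer$gamma * 0, beta = layer$beta * 0))
  }
}

upsample_idx <- function(dims_out) {
  half <- dims_out %/% 2L
  ind <- arrayInd(seq_len(prod(dims_out)), dims_out)
  src <- (ind - 1L) %/% 2L
  as.integer(src[, 1] + half[1] * (src[, 2] + half[2] * src[, 3]) + 1L)
}

unet_forward <- function(model, x, dims, training = TRUE) {
  D <- model$config$depth
  caches <- list(enc = vector("list", D + 1), pool = vector("list", D),
                 dec = vector("list", D), dims = vector("list", D + 1))
  skips <- vector("list", D + 1)
  cur <- x
  cur_dims <- dims
  for (l in 0:D) {
    caches$dims[[l + 1]] <- cur_dims
    nrm <- model$config$normalization
    neps <- model$config$norm_eps %||% 1e-5
    ba <- conv_block_fwd(model$enc[[l + 1]]$a, cur, cur_dims, nrm,
                         training, neps)
    bb <- conv_block_fwd(model$enc[[l + 1]]$b, ba$out, cur_dims, nrm,
                         training, neps)
    model$enc[[l + 1]]$a <- ba$layer
    model$enc[[l + 1]]$b <- bb$layer
    caches$enc[[l + 1]] <- list(a = ba$cache, b = bb$cache)
    skips[[l + 1]] <- bb$out
    if (l < D) {
      mp <- cpp_maxpool_forward(bb$out, cur_dims)
      caches$pool[[l + 1]] <- list(argmax = mp$argmax,
                                   n_in = ncol(bb$out))
      cur <- mp$y
      cur_dims <- cur_dims %/% 2L
    } else {
      cur <- bb$out
    }
  }
  for (s in seq_len(D)) {        # decoder stages, deep to shallow
    l <- D - s                   # target level
    tdims <- caches$dims[[l + 1]]
    idx <- upsample_idx(tdims)
    up_in <- cur[, idx, drop = FALSE]
    nrm <- model$config$normalization
    neps <- model$config$norm_eps %||% 1e-5
    bu <- conv_block_fwd(model$dec[[s]]$up, up_in, tdims, nrm, training,
                         neps)
    cat_in <- rbind(skips[[l + 1]], bu$out)
    ba <- conv_block_fwd(model$dec[[s]]$a, cat_in, tdims, nrm, training,
                         neps)
    bb <- conv_block_fwd(model$dec[[s]]$b, ba$out, tdims, nrm, training,
                         neps)
    model$dec[[s]]$up <- bu$layer
    model$dec[[s]]$a <- ba$layer
    model$dec[[s]]$b <- bb$layer
    caches$dec[[s]] <- list(up = bu$cache, a = ba$cache, b = bb$cache,
                            idx = idx, n_skip = nrow(skips[[l + 1]]),
                            n_cur = ncol(cur))
    cur <- bb$out
  }
  logits <- model$head$W %*% cur + model$head$b
  caches$head_in <- cur
  list(logits = logits, caches = caches, model = model)
}

softmax_cols <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

unet_backward <- function(model, caches, dlogits) {
  D <- model$config$depth
  grads <- list(enc = vector("list", D + 1), dec = vector("list", D))
  grads$head <- list(W = dlogits %*% t(caches$head_in),
                     b = rowSums(dlogits))
  dcur <- t(model$head$W) %*% dlogits
  skip_grads <- vector("list", D + 1)
  for (s in rev(seq_len(D))) {      # stage s targets level l = D - s
    cc <- caches$dec[[s]]
    gb <- conv_block_bwd(model$dec[[s]]$b, cc$b, dcur)
    ga <- conv_block_bwd(model$dec[[s]]$a, cc$a, gb$dx)
    dskip <- ga$dx[seq_len(cc$n_skip), , drop = FALSE]
    dup_out <- ga$dx[-seq_len(cc$n_skip), , drop = FALSE]
    gu <- conv_block_bwd(model$dec[[s]]$up, cc$up, dup_out)
    # NN upsample backward: sum gradient over each 2x2x2 output block
    dcur <- t(rowsum(t(gu$dx), group = cc$idx))
    grads$dec[[s]] <- list(up = gu$grads, a = ga$grads, b = gb$grads)
    skip_grads[[(D - s) + 1]] <- dskip
  }
  for (l in rev(0:D)) {
    cc <- caches$enc[[l + 1]]
    if (l < D) {
      pool <- caches$pool[[l + 1]]
      dout <- cpp_maxpool_backward(dcur, pool$argmax, pool$n_in) +
        skip_grads[[l + 1]]
    } else {
      dout <- dcur
    }
    gb <- conv_block_bwd(model$enc[[l + 1]]$b, cc$b, dout)
    ga <- conv_block_bwd(model$enc[[l + 1]]$a, cc$a, gb$dx)
    grads$enc[[l + 1]] <- list(a = ga$grads, b = gb$grads)
    dcur <- ga$dx
  }
  grads
}

# ---- optimizer ---------------------------------------------------------

rmsprop_init <- function(model) {
  zero_like <- function(p) lapply(p, function(v) v * 0)
  list(enc = lapply(model$enc, function(lv) lapply(lv, zero_like)),
       dec = lapply(model$dec, function(lv) lapply(lv, zero_like)),
       head = zero_like(model$head))
}

rmsprop_update_layer <- function(layer, grad, state, lr, rho = 0.9,
                                 eps = 1e-8) {
  for (nm in names(grad)) {
    state[[nm]] <- rho * state[[nm]] + (1 - rho) * grad[[nm]]^2
    layer[[nm]] <- layer[[nm]] - lr * grad[[nm]] / sqrt(state[[nm]] + eps)
  }
  list(layer = layer, state = state)
}

rmsprop_step <- function(model, grads, opt, lr) {
  for (l in seq_along(model$enc))
    for (nm in names(model$enc[[l]])) {
      r <- rmsprop_update_layer(model$enc[[l]][[nm]], grads$enc[[l]][[nm]],
                                opt$enc[[l]][[nm]], lr)
      model$enc[[l]][[nm]] <- r$layer
      opt$enc[[l]][[nm]] <- r$state
    }
  for (s in seq_along(model$dec))
    for (nm in names(model$dec[[s]])) {
      r <- rmsprop_update_layer(model$dec[[s]][[nm]], grads$dec[[s]][[nm]],
                                opt$dec[[s]][[nm]], lr)
      model$dec[[s]][[nm]] <- r$layer
      opt$dec[[s]][[nm]] <- r$state
    }
  r <- rmsprop_update_layer(model$head, grads$head, opt$head, lr)
  model$head <- r$layer
  opt$head <- r$state
  list(model = model, opt = opt)
}
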