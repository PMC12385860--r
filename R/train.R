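#' Sample a random aligned crop from a volume/label pair
#'
#' Crop origins are drawn uniformly over all valid positions. When the
#' patch exceeds the volume along an axis, both volumes are zero-origin
#' padded (image with `fill`, labels with background) before cropping.
#'
#' @param volume an [image_volume()].
#' @param labels the aligned [label_volume()].
#' @param patch integer length-3 crop size (voxels).
#' @param seed optional seed; `NULL` uses (and advances) the current RNG.
#' @param fill pad value for the image (HU).
#' @return List with `image`, `labels` (arrays) and `origin` (1-based
#'   voxel index of the crop corner in the padded volume).
#' @export
sample_crop <- function(volume, labels, patch, seed = NULL, fill = -1024) {
  stop_if_grid_mismatch(volume, labels, "volume and labels")
  patch <- as.integer(patch)
  draw <- function() {
    d <- dim(volume$voxels)
    img <- volume$voxels
    lab <- labels$voxels
    if (any(patch > d)) {
      pd <- pmax(d, patch)
      pimg <- array(fill, dim = pd)
      plab <- array(0L, dim = pd)
      pimg[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- img
      plab[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- lab
      img <- pimg
      lab <- plab
      d <- pd
    }
    hi <- d - patch + 1L
    orig <- vapply(hi, function(h) if (h == 1L) 1L else
      sample.int(h, 1L), 1L)
    ix <- Map(function(o, p) o:(o + p - 1L), orig, patch)
    list(image = img[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
         labels = lab[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
         origin = orig)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# training crop: uniform over valid origins, or — with probability
# fg_crop_bias — uniform among the origins whose window CONTAINS a random
# foreground voxel. Containment, not centering: the organ must appear at
# every window offset or the network learns position-in-window artifacts.
training_crop <- function(volume, labels, config) {
  d <- dim(labels$voxels)
  if (all(config$patch <= d) && runif(1) < config$fg_crop_bias) {
    present <- intersect(1:3, unique(as.vector(labels$voxels)))
    if (length(present) > 0) {
      cl <- present[sample.int(length(present), 1L)]
      vox <- which(labels$voxels == cl)
      v <- vox[sample.int(length(vox), 1L)]
      ijk <- as.integer(arrayInd(v, d))
      lo <- pmax(ijk - config$patch + 1L, 1L)
      hi <- pmin(ijk, d - config$patch + 1L)
      orig <- lo + vapply(hi - lo, function(w)
        sample.int(w + 1L, 1L) - 1L, 1L)
      ix <- Map(function(o, p) o:(o + p - 1L), orig, config$patch)
      return(list(image = volume$voxels[ix[[1]], ix[[2]], ix[[3]],
                                        drop = FALSE],
                  labels = labels$voxels[ix[[1]], ix[[2]], ix[[3]],
                                         drop = FALSE],
                  origin = orig))
    }
  }
  sample_crop(volume, labels, config$patch)
}

# build the network input (channels x voxels) for a crop: normalized HU
# plus, optionally, the crop's normalized physical coordinates within the
# full volume (so patches carry global position)
crop_input <- function(crop_img, origin, full_dim, spacing, config) {
  x <- matrix(normalize_hu(crop_img, config$hu_window), nrow = 1)
  if (config$coord_features) {
    d <- dim(crop_img)
    half <- pmax((full_dim - 1) * spacing / 2, 1e-6)
    ind <- arrayInd(seq_len(prod(d)), d)
    coords <- sweep(ind - 1 + matrix(origin - 1, nrow(ind), 3,
                                     byrow = TRUE), 2, spacing, "*")
    coords <- sweep(coords, 2, (full_dim - 1) * spacing / 2, "-")
    coords <- sweep(coords, 2, half, "/")
    x <- rbind(x, t(coords))
  }
  x
}

# validation loss: deterministic crops centred on each foreground class's
# centroid (so the sparse organ classes are represented in the Dice
# terms) plus the volume centre
eval_loss <- function(model, volume, labels, config) {
  d <- dim(volume$voxels)
  if (any(config$patch > d))
    return(eval_loss_crop(model, sample_crop(volume, labels, config$patch,
                                             seed = 0L), d, volume,
                          config))
  centres <- list((d + 1L) %/% 2L)
  for (cl in 1:3) {
    vox <- which(labels$voxels == cl)
    if (length(vox) > 0) {
      # organ voxel nearest the class centroid (the centroid itself can
      # fall outside, e.g. between the two kidneys)
      ind <- arrayInd(vox, d)
      ctr <- colMeans(ind)
      v <- which.min(rowSums(sweep(ind, 2, ctr, "-")^2))
      centres[[length(centres) + 1L]] <- as.integer(ind[v, ])
    }
  }
  losses <- vapply(centres, function(ctr) {
    orig <- pmin(pmax(ctr - config$patch %/% 2L, 1L), d - config$patch + 1L)
    ix <- Map(function(o, p) o:(o + p - 1L), orig, config$patch)
    cr <- list(image = volume$voxels[ix[[1]], ix[[2]], ix[[3]],
                                     drop = FALSE],
               labels = labels$voxels[ix[[1]], ix[[2]], ix[[3]],
                                      drop = FALSE],
               origin = orig)
    eval_loss_crop(model, cr, d, volume, config)
  }, 0)
  mean(losses)
}

eval_loss_crop <- function(model, cr, d, volume, config) {
  x <- crop_input(cr$image, cr$origin, d, volume$spacing, config)
  fw <- unet_forward(model, x, config$patch, training = FALSE)
  prob <- softmax_cols(fw$logits)
  g <- onehot_encode(as.integer(cr$labels), config$n_classes)
  dice_loss(prob, g, config$dice_eps)
}

#' Train a cross-validated U-Net ensemble
#'
#' Volumes are assigned to folds by a seeded permutation. For each fold, a
#' model is trained on the other folds' volumes (the held-out fold is the
#' validation portion); every epoch runs `steps_per_epoch` gradient steps
#' on random crops (one crop per step) with RMSProp on the categorical
#' Dice loss, and the retained model is the epoch with the best (lowest)
#' validation loss. The per-fold models form an averaging ensemble.
#'
#' @param dataset list of cases, each `list(image =, labels =)` with
#'   aligned [image_volume()] / [label_volume()]; length `>=` folds.
#' @param config a [unet_config()].
#' @param seed integer seed controlling fold assignment, initialization
#'   and crop sampling.
#' @param verbose print per-epoch validation losses?
#' @return A `trained_ensemble`: `models` (per fold: `weights`,
#'   `best_epoch`, `best_val_loss`, `val_history`), `fold_assignment`,
#'   `config`, `seed`.
#' @export
train_cross_validation <- function(dataset, config = unet_config("small"),
                                   seed = 1L, verbose = FALSE) {
  n <- length(dataset)
  if (n < config$folds)
    stop("dataset (", n, ") smaller than number of folds (", config$folds,
         ")")
  for (case in dataset)
    stop_if_grid_mismatch(case$image, case$labels, "image and labels")
  assignment <- with_seed(seed, sample(rep_len(seq_len(config$folds), n)))
  models <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    train_idx <- which(assignment != f)
    val_idx <- which(assignment == f)
    model <- unet_init(config, seed = seed * 1000L + f)
    opt <- rmsprop_init(model)
    best <- list(loss = Inf, epoch = 0L, weights = NULL)
    history <- numeric(config$epochs)
    with_seed(seed * 100L + f, {
      for (epoch in seq_len(config$epochs)) {
        # polynomial decay (exponent 0.9) settles the late epochs
        lr_now <- config$lr * (1 - (epoch - 1) / config$epochs)^0.9
        for (step in seq_len(config$steps_per_epoch)) {
          case <- dataset[[train_idx[sample.int(length(train_idx), 1L)]]]
          cr <- training_crop(case$image, case$labels, config)
          x <- crop_input(cr$image, cr$origin, dim(case$image$voxels),
                          case$image$spacing, config)
          fw <- unet_forward(model, x, config$patch, training = TRUE)
          model <- fw$model        # running normalization statistics
          prob <- softmax_cols(fw$logits)
          g <- onehot_encode(as.integer(cr$labels), config$n_classes)
          dprob <- dice_loss_grad(prob, g, config$dice_eps)
          dlogits <- prob * (dprob -
            matrix(colSums(dprob * prob), nrow(prob), ncol(prob),
                   byrow = TRUE))
          if (config$ce_weight > 0)
            dlogits <- dlogits +
              config$ce_weight * (prob - g) / ncol(g)
          grads <- unet_backward(model, fw$caches, dlogits)
          r <- rmsprop_step(model, grads, opt, lr_now)
          model <- r$model
          opt <- r$opt
        }
        vloss <- mean(vapply(val_idx, function(i)
          eval_loss(model, dataset[[i]]$image, dataset[[i]]$labels,
                    config), 0))
        history[epoch] <- vloss
        if (vloss < best$loss)
          best <- list(loss = vloss, epoch = epoch, weights = model)
        if (verbose)
          message(sprintf("fold %d epoch %d: val dice loss %.4f", f,
                          epoch, vloss))
      }
    })
    models[[f]] <- list(weights = best$weights, best_epoch = best$epoch,
                        best_val_loss = best$loss, val_history = history)
  }
  structure(list(models = models, fold_assignment = assignment,
                 config = config, seed = seed),
            class = "trained_ensemble")
}

sliding_origins <- function(n, patch, stride) {
  if (patch >= n) return(1L)
  o <- seq.int(1L, n - patch + 1L, by = stride)
  if (o[length(o)] != n - patch + 1L) o <- c(o, n - patch + 1L)
  o
}

#' Sliding-window class probabilities for a volume
#'
#' Tiles the volume with patches at the configured stride, predicts each
#' window with every fold model, and averages the probabilities of all
#' contributing windows and folds per voxel (uniform weights) — no
#' downsampling of the scan. Volumes smaller than a patch are padded for
#' prediction and cropped back.
#'
#' @param ensemble a `trained_ensemble`.
#' @param volume an [image_volume()]; resampled internally to the working
#'   spacing when it differs.
#' @param stride optional stride override (voxels, length 3).
#' @return 4-D array `(class, x, y, z)` of averaged probabilities on the
#'   (possibly resampled) working grid, with the working grid geometry
#'   attached as attributes.
#' @export
predict_probabilities <- function(ensemble, volume, stride = NULL) {
  stopifnot(inherits(ensemble, "trained_ensemble"))
  if (length(ensemble$models) == 0) stop("empty ensemble")
  config <- ensemble$config
  work <- if (max(abs(volume$spacing - config$spacing)) > 1e-6)
    resample(volume, config$spacing) else volume
  d0 <- dim(work$voxels)
  patch <- config$patch
  pd <- pmax(d0, patch)
  padded <- work
  if (any(pd > d0)) {
    arr <- array(-1024, dim = pd)
    arr[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- work$voxels
    padded <- image_volume(arr, work$spacing, work$origin)
  }
  d <- dim(padded$voxels)
  stride <- as.integer(stride %||% config$stride)
  origins <- expand.grid(x = sliding_origins(d[1], patch[1], stride[1]),
                         y = sliding_origins(d[2], patch[2], stride[2]),
                         z = sliding_origins(d[3], patch[3], stride[3]))
  pm <- matrix(0, config$n_classes, prod(d))
  count <- numeric(prod(d))
  for (w in seq_len(nrow(origins))) {
    o <- as.integer(unlist(origins[w, ]))
    ix <- Map(function(a, p) a:(a + p - 1L), o, patch)
    crop <- padded$voxels[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    x <- crop_input(crop, o, d, padded$spacing, config)
    ind <- as.vector(outer(ix[[1]], outer((ix[[2]] - 1L) * d[1],
                                          (ix[[3]] - 1L) * d[1] * d[2],
                                          "+"), "+"))
    for (m in ensemble$models) {
      fw <- unet_forward(m$weights, x, patch, training = FALSE)
      pm[, ind] <- pm[, ind] + softmax_cols(fw$logits)
    }
    count[ind] <- count[ind] + length(ensemble$models)
  }
  pm <- sweep(pm, 2, pmax(count, 1), "/")
  pm <- pm[, as.vector(outer(seq_len(d0[1]),
                             outer((seq_len(d0[2]) - 1L) * d[1],
                                   (seq_len(d0[3]) - 1L) * d[1] * d[2],
                                   "+"), "+")), drop = FALSE]
  out <- array(pm, dim = c(config$n_classes, d0))
  attr(out, "spacing") <- work$spacing
  attr(out, "origin") <- work$origin
  out
}

#' Segment a volume with a trained ensemble
#'
#' Runs [predict_probabilities()] and takes the per-voxel argmax (ties:
#' lowest class). The output label volume is produced on the input
#' volume's original grid (nearest-neighbour mapping back when internal
#' resampling was needed).
#'
#' @param object a `trained_ensemble`.
#' @param volume an [image_volume()].
#' @param stride optional stride override.
#' @param ... unused.
#' @return A [label_volume()] on `volume`'s grid.
#' @export
predict.trained_ensemble <- function(object, volume, stride = NULL, ...) {
  probs <- predict_probabilities(object, volume, stride)
  d <- dim(probs)[-1]
  lab <- max.col(t(matrix(probs, nrow = dim(probs)[1])),
                 ties.method = "first") - 1L
  out <- label_volume(array(as.integer(lab), dim = d),
                      attr(probs, "spacing"), attr(probs, "origin"))
  if (max(abs(volume$spacing - out$spacing)) > 1e-6 ||
      !identical(dim(volume$voxels), d)) {
    out <- resample_onto(out, grid_of(volume))
  }
  out
}

#' Dice overlap between two label volumes
#'
#' @param pred,truth [label_volume()] objects on the same grid.
#' @param classes classes to score (default foreground 1:3).
#' @return Named vector of per-class Dice coefficients plus `"mean"`
#'   (classes absent from both volumes score `NA` and are dropped from
#'   the mean).
#' @export
dice_score <- function(pred, truth, classes = 1:3) {
  stop_if_grid_mismatch(pred, truth, "pred and truth")
  p <- as.integer(pred$voxels)
  g <- as.integer(truth$voxels)
  per <- vapply(classes, function(cl) {
    np <- sum(p == cl)
    ng <- sum(g == cl)
    if (np + ng == 0) return(NA_real_)
    2 * sum(p == cl & g == cl) / (np + ng)
  }, 0)
  names(per) <- paste0("class", classes)
  c(per, mean = mean(per, na.rm = TRUE))
}
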