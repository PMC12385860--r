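test_that("unet_config validates patch divisibility and fold counts", {
  expect_error(unet_config("small", patch = c(30, 32, 16)), "divisible")
  expect_error(unet_config("small", folds = 1), "folds")
  expect_error(unet_config("small", epochs = 0), "epoch")
  full <- unet_config("full")
  expect_identical(full$patch, c(192L, 160L, 128L))
  expect_equal(full$spacing, c(1, 1, 2))
  expect_identical(full$folds, 5L)
  expect_identical(full$epochs, 250L)
  expect_equal(full$lr, 1e-4)
  expect_identical(full$optimizer, "rmsprop")
})

test_that("sample_crop is aligned, seeded and uniform over valid origins", {
  ph <- plain_phantom()
  cfg <- unet_config("small")
  # degenerate crop: patch equal to the full volume returns the volume
  full <- sample_crop(ph$ctu, ph$truth, dim(ph$ctu$voxels), seed = 1)
  expect_identical(full$image, ph$ctu$voxels)
  expect_identical(full$labels, ph$truth$voxels)
  # determinism
  a <- sample_crop(ph$ctu, ph$truth, cfg$patch, seed = 11)
  b <- sample_crop(ph$ctu, ph$truth, cfg$patch, seed = 11)
  expect_identical(a$origin, b$origin)
  # alignment: the label crop matches the image crop's position
  ix <- Map(function(o, p) o:(o + p - 1L), a$origin, cfg$patch)
  expect_identical(a$labels, ph$truth$voxels[ix[[1]], ix[[2]], ix[[3]]])
  expect_error(sample_crop(ph$ctu,
                           label_volume(array(0L, c(4, 4, 4))),
                           cfg$patch), "grid")

  # marginal origin distribution uniform over the 9 valid positions
  vol <- image_volume(array(rnorm(16^3), c(16, 16, 16)))
  lab <- label_volume(array(0L, c(16, 16, 16)))
  set.seed(99)
  origins <- t(replicate(1000, sample_crop(vol, lab, c(8, 8, 8))$origin))
  for (axis in 1:3) {
    tab <- tabulate(origins[, axis], nbins = 9)
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    expect_gt(p, 1e-4)
  }
})

test_that("dice loss matches closed-form values and stays within bounds", {
  # perfect prediction -> loss ~ 0
  g <- focusctu:::onehot_encode(c(0L, 1L, 2L, 3L, 0L, 1L), 4)
  expect_lt(dice_loss(g, g), 1e-5)
  # uniform prediction on all-background truth, closed form:
  # background dice = (2 * N/4) / (N/4 + N) = 0.4, others ~ 0
  n <- 400
  prob <- matrix(0.25, 4, n)
  gbg <- focusctu:::onehot_encode(rep(0L, n), 4)
  expect_equal(dice_loss(prob, gbg), 1 - 0.4 / 4, tolerance = 1e-4)
  expect_error(dice_loss(prob, gbg[, 1:10]), "shapes")
  # bounds on random inputs
  set.seed(5)
  for (i in 1:20) {
    p <- matrix(runif(4 * 50), 4)
    p <- sweep(p, 2, colSums(p), "/")
    gr <- focusctu:::onehot_encode(sample(0:3, 50, TRUE), 4)
    l <- dice_loss(p, gr)
    expect_gte(l, 0)
    expect_lte(l, 1)
  }
})

test_that("dice loss gradient agrees with finite differences", {
  set.seed(8)
  p <- matrix(runif(4 * 30), 4)
  p <- sweep(p, 2, colSums(p), "/")
  g <- focusctu:::onehot_encode(sample(0:3, 30, TRUE), 4)
  an <- focusctu:::dice_loss_grad(p, g)
  h <- 1e-6
  for (idx in list(c(1, 3), c(2, 17), c(4, 30))) {
    pp <- p
    pp[idx[1], idx[2]] <- pp[idx[1], idx[2]] + h
    pm <- p
    pm[idx[1], idx[2]] <- pm[idx[1], idx[2]] - h
    num <- (dice_loss(pp, g) - dice_loss(pm, g)) / (2 * h)
    expect_equal(an[idx[1], idx[2]], num, tolerance = 1e-4)
  }
})

test_that("sliding-window probabilities average contributing windows", {
  cfg <- unet_config("small", patch = c(32, 32, 16))
  ens <- random_ensemble(cfg)
  vol <- image_volume(array(rnorm(48 * 32 * 16, 40, 30), c(48, 32, 16)),
                      cfg$spacing)
  # stride 16 along x -> windows at x = 1 and x = 17 only
  probs <- predict_probabilities(ens, vol, stride = c(16, 32, 16))
  # hand-computed two-window average in the overlap region
  w1 <- vol$voxels[1:32, , , drop = FALSE]
  w2 <- vol$voxels[17:48, , , drop = FALSE]
  fw <- function(crop, origin) {
    x <- focusctu:::crop_input(crop, origin, dim(vol$voxels), vol$spacing,
                               cfg)
    focusctu:::softmax_cols(
      focusctu:::unet_forward(ens$models[[1]]$weights, x, cfg$patch)$logits)
  }
  p1 <- array(fw(w1, c(1, 1, 1)), c(4, 32, 32, 16))
  p2 <- array(fw(w2, c(17, 1, 1)), c(4, 32, 32, 16))
  # voxel x = 20 lies in both windows; x = 5 only in the first
  expect_equal(probs[, 20, 10, 8],
               (p1[, 20, 10, 8] + p2[, 4, 10, 8]) / 2, tolerance = 1e-10)
  expect_equal(probs[, 5, 10, 8], p1[, 5, 10, 8], tolerance = 1e-10)
  # probabilities are normalized per voxel
  expect_equal(colSums(matrix(probs, 4)), rep(1, 48 * 32 * 16),
               tolerance = 1e-8)
})

test_that("prediction is invariant to model order and single-fold identity", {
  cfg <- unet_config("small", patch = c(16, 16, 8), base_channels = 4)
  e2 <- random_ensemble(cfg, n_models = 2)
  vol <- image_volume(array(rnorm(24 * 16 * 8, 40, 30), c(24, 16, 8)),
                      cfg$spacing)
  p12 <- predict_probabilities(e2, vol)
  e21 <- e2
  e21$models <- rev(e21$models)
  expect_equal(predict_probabilities(e21, vol), p12, tolerance = 1e-12)
  # single-model ensemble equals that model's prediction
  e1 <- e2
  e1$models <- e2$models[1]
  p1 <- predict_probabilities(e1, vol)
  expect_false(isTRUE(all.equal(p1, p12)))
  expect_identical(dim(p1), dim(p12))
})

test_that("prediction handles volumes smaller than a patch and air input", {
  cfg <- unet_config("small", patch = c(16, 16, 8), base_channels = 4)
  ens <- random_ensemble(cfg)
  tiny <- image_volume(array(rnorm(10 * 12 * 6, 40, 30), c(10, 12, 6)),
                       cfg$spacing)
  lab <- predict(ens, tiny)
  expect_identical(dim(lab$voxels), dim(tiny$voxels))
  air <- image_volume(array(-1024, c(16, 16, 8)), cfg$spacing)
  lab_air <- predict(ens, air)
  expect_true(all(lab_air$voxels %in% 0:3))
  empty <- ens
  empty$models <- list()
  expect_error(predict(empty, tiny), "empty ensemble")
})

test_that("cross-validation trains, selects best epochs, and overfits phantoms", {
  dataset <- training_phantoms()
  expect_error(train_cross_validation(dataset[1:1], unet_config("small")),
               "smaller than")
  ens <- overfit_ensemble()
  cfg <- ens$config
  expect_length(ens$models, cfg$folds)
  # deterministic fold assignment
  ens_seed <- with(ens, fold_assignment)
  again <- focusctu:::with_seed(ens$seed,
    sample(rep_len(seq_len(cfg$folds), length(dataset))))
  expect_identical(ens_seed, again)
  for (m in ens$models) {
    # retained model is the best-validation-loss epoch
    expect_equal(m$best_val_loss, min(m$val_history))
    expect_identical(m$best_epoch, which.min(m$val_history))
    expect_lte(m$best_val_loss, m$val_history[1])
  }
  # training-set segmentation quality (overfit sanity): mean foreground
  # Dice across the training phantoms
  ds <- vapply(dataset, function(case)
    dice_score(predict(ens, case$image), case$labels)[["mean"]], 0)
  expect_gte(mean(ds), 0.80)
})

test_that("models generalize to the phantom anatomy their fold never saw", {
  # cross-validation gives held-out predictions for free: score each
  # phantom with the model of the fold that excluded it
  dataset <- training_phantoms()
  ens <- overfit_ensemble()
  per_class <- sapply(seq_along(dataset), function(i) {
    f <- ens$fold_assignment[i]
    other <- ens
    other$models <- ens$models[-f]
    dice_score(predict(other, dataset[[i]]$image), dataset[[i]]$labels)
  })
  kidney <- mean(per_class["class1", ])
  bladder <- mean(per_class["class3", ])
  expect_gte(kidney, 0.6)
  expect_gte(bladder, 0.6)
})
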