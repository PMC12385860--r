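test_that("method 1 is exactly the nonzero-label mask", {
  empty <- label_volume(array(0L, c(6, 6, 6)))
  expect_false(any(method1_mask(empty)))
  one <- array(0L, c(6, 6, 6))
  one[3, 4, 5] <- 1L
  m <- method1_mask(label_volume(one))
  expect_identical(which(m), which(one == 1L))
  ph <- plain_phantom()
  expect_identical(sum(method1_mask(ph$observed)),
                   sum(ph$observed$voxels > 0))
})

test_that("method 2 matches brute-force physical-distance dilation", {
  set.seed(31)
  d <- c(14, 12, 10)
  mask <- array(FALSE, d)
  mask[cbind(sample(d[1], 6, TRUE), sample(d[2], 6, TRUE),
             sample(d[3], 6, TRUE))] <- TRUE
  for (spacing in list(c(1, 1, 1), c(1, 1, 2), c(2, 1.5, 1))) {
    for (r in c(2, 3.5, 6)) {
      expect_identical(dilate_mm(mask, r, spacing),
                       brute_force_dilation(mask, r, spacing),
                       label = sprintf("spacing %s radius %g",
                                       paste(spacing, collapse = "x"), r))
    }
  }
})

test_that("boundary 0 degenerates to method 1 and dilation is monotone", {
  ph <- gapped_phantom()
  expect_identical(method2_mask(ph$observed, 0), method1_mask(ph$observed))
  m10 <- method2_mask(ph$observed, 10)
  m20 <- method2_mask(ph$observed, 20)
  expect_true(all(m20[m10]))
})

test_that("connected tracts pass through bridge_components unchanged", {
  ph <- plain_phantom()
  br <- bridge_components(ph$observed)
  expect_identical(br$mask, method1_mask(ph$observed))
  expect_length(br$bridges, 0)
})

test_that("bridging reconnects gapped ureters with sensible segments", {
  ph <- gapped_phantom()
  br <- bridge_components(ph$observed)
  expect_length(br$bridges, 1)
  cc <- igraph_components(br$mask)
  expect_identical(cc$n, 1L)
  # the bridge spans the nearest-surface distance between the two
  # observed components (exhaustive oracle), within two voxel diagonals
  obs <- igraph_components(ph$observed$voxels > 0)
  stopifnot(obs$n == 2)
  mm1 <- focusctu:::linear_to_mm(ph$observed, which(obs$membership == 1))
  mm2 <- focusctu:::linear_to_mm(ph$observed, which(obs$membership == 2))
  oracle <- brute_force_nearest(mm1, mm2)
  expect_lt(abs(br$bridges[[1]]$length_mm - oracle$distance),
            2 * sqrt(sum(ph$observed$spacing^2)))

  ph2 <- double_gap_phantom()
  br2 <- bridge_components(ph2$observed)
  expect_length(br2$bridges, 2)
  expect_identical(igraph_components(br2$mask)$n, 1L)
})

test_that("bridge endpoints lie on the surface of distinct components", {
  ph <- double_gap_phantom()
  br <- bridge_components(ph$observed)
  comp <- igraph_components(ph$observed$voxels > 0)$membership
  surf <- which(focusctu:::surface_voxels(ph$observed$voxels > 0))
  surf_mm <- focusctu:::linear_to_mm(ph$observed, surf)
  for (b in br$bridges) {
    ends <- rbind(b$from, b$to)
    comp_of_end <- apply(ends, 1, function(p) {
      dd <- rowSums(sweep(surf_mm, 2, p, "-")^2)
      comp[surf[which.min(dd)]]
    })
    expect_equal(min(rowSums(sweep(surf_mm, 2, ends[1, ], "-")^2)), 0)
    expect_equal(min(rowSums(sweep(surf_mm, 2, ends[2, ], "-")^2)), 0)
  }
  # at most (initial components - 1) merges
  expect_lte(length(br$bridges),
             igraph_components(ph$observed$voxels > 0)$n - 1)
})

test_that("bridging warns when kidney or bladder labels are absent", {
  arr <- array(0L, c(12, 6, 6))
  arr[2:3, 3, 3] <- 2L
  arr[9:10, 3, 3] <- 2L
  expect_warning(br <- bridge_components(label_volume(arr, c(2, 2, 2))),
                 "lack kidney or bladder")
  expect_identical(attr(connected_components(br$mask), "n_components"), 1L)
  expect_error(bridge_components(label_volume(array(0L, c(4, 4, 4)))),
               "no urinary-tract voxels")
})

test_that("method 3 equals method 2 when no gaps exist, else a superset", {
  ph <- plain_phantom()
  m3 <- method3_mask(ph$observed)
  expect_identical(as.vector(m3), as.vector(method2_mask(ph$observed)))
  gp <- gapped_phantom()
  m2g <- method2_mask(gp$observed)
  m3g <- method3_mask(gp$observed)
  expect_true(all(m3g[m2g]))
  expect_gt(sum(m3g), sum(m2g))
  # every gap voxel near the bridge path is inside the mask
  cfg <- focused_view_config()
  bridges <- attr(m3g, "bridges")
  gap_vox <- which(gp$truth$voxels == 2L & gp$observed$voxels == 0L)
  gap_mm <- focusctu:::linear_to_mm(gp$truth, gap_vox)
  seg <- bridges[[1]]
  # distance from each gap voxel to the bridge segment
  ab <- seg$to - seg$from
  t <- pmin(1, pmax(0, (sweep(gap_mm, 2, seg$from, "-") %*% ab) /
                      sum(ab^2)))
  dd <- sqrt(rowSums((sweep(gap_mm, 2, seg$from, "-") - outer(c(t), ab))^2))
  near <- dd <= cfg$bridge_radius_mm - max(gp$truth$spacing)
  expect_true(all(m3g[gap_vox[near]]))
})

test_that("mask application copies inside and fills outside, idempotently", {
  ph <- plain_phantom()
  full <- array(TRUE, dim(ph$ctu$voxels))
  none <- !full
  expect_identical(apply_mask(ph$ctu, full)$voxels, ph$ctu$voxels)
  expect_true(all(apply_mask(ph$ctu, none, -1024)$voxels == -1024))
  m <- method2_mask(ph$observed, 10)
  once <- apply_mask(ph$ctu, m)
  expect_identical(apply_mask(once, m), once)
  expect_identical(once$voxels[m], ph$ctu$voxels[m])
  expect_true(all(once$voxels[!m] == -1024))
  expect_error(apply_mask(ph$ctu, array(TRUE, c(2, 2, 2))), "grid")
})

test_that("focused_view with identity registration equals direct masking", {
  ph <- plain_phantom()
  fv <- focused_view(ph$ctu, ph$unenhanced, ph$observed,
                     focused_view_config(method = 2),
                     registration = "identity")
  expect_identical(fv$masked_ctu$voxels,
                   apply_mask(ph$ctu, fv$mask)$voxels)
  expect_equal(fv$masked_unenhanced$voxels,
               apply_mask(ph$unenhanced, fv$mask)$voxels,
               tolerance = 1e-12)
  expect_true(all(fv$masked_ctu$voxels[!fv$mask] == -1024))
})

test_that("lesion concealment survives registration of a misaligned pair", {
  ph <- generate_phantom(default_spec(
    "small", seed = 41,
    gaps = list(list(side = "left", start_fraction = 0.5, length_mm = 12)),
    lesions = list(list(center = c(36, 48, 90), radius_mm = 6, hu = 80)),
    misalignment = "default"))
  fv <- focused_view(ph$ctu, ph$unenhanced, ph$observed,
                     focused_view_config(method = 3))
  res <- concealment_check(ph$incidental_mask, fv$mask)
  expect_true(res$all_hidden)
  # the registered, masked unenhanced volume carries no lesion voxels
  expect_true(all(fv$masked_unenhanced$voxels[ph$incidental_mask] == -1024))
  # and the recovered transform is close to the applied misalignment
  dev <- deviation_from(fv$transform, ph$misalignment, ph$ctu)
  expect_lt(dev$translation_mm, 1)
  expect_lt(dev$rotation_deg, 1)
})

test_that("method 3 reveals strictly more tract than method 1 on gapped input", {
  gp <- gapped_phantom()
  fv1 <- focused_view(gp$ctu, gp$unenhanced, gp$observed,
                      focused_view_config(method = 1),
                      registration = "identity")
  fv3 <- focused_view(gp$ctu, gp$unenhanced, gp$observed,
                      focused_view_config(method = 3),
                      registration = "identity")
  expect_true(all(fv3$mask[fv1$mask]))
  tract_truth <- gp$truth$voxels > 0
  expect_gt(sum(fv3$mask & tract_truth), sum(fv1$mask & tract_truth))
})
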