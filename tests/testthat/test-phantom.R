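test_that("noiseless untextured phantom is piecewise constant with observed == truth", {
  spec <- default_spec("small", noise_sd = 0)
  spec$texture_amp_hu <- 0
  ph <- generate_phantom(spec)
  expect_identical(ph$observed$voxels, ph$truth$voxels)
  pal <- c(spec$air_hu, spec$background_hu, spec$unopacified_hu,
           spec$contrast_hu)
  expect_true(all(as.vector(ph$ctu$voxels) %in% pal))
  expect_true(all(as.vector(ph$unenhanced$voxels) %in% pal))
})

test_that("same spec and seed give bit-identical phantoms", {
  a <- generate_phantom(default_spec("small", seed = 9))
  b <- generate_phantom(default_spec("small", seed = 9))
  expect_identical(a$ctu$voxels, b$ctu$voxels)
  expect_identical(a$unenhanced$voxels, b$unenhanced$voxels)
  expect_identical(a$truth$voxels, b$truth$voxels)
  # and default_spec itself is deterministic
  expect_identical(default_spec("small", seed = 9),
                   default_spec("small", seed = 9))
})

test_that("observed labels are a voxel-wise subset of truth", {
  ph <- double_gap_phantom()
  obs <- ph$observed$voxels
  expect_true(all(obs == 0L | obs == ph$truth$voxels))
})

test_that("a ureter gap splits the observed tract (flood-fill oracle)", {
  ph <- gapped_phantom()
  # observed tract loses connectivity; the independent igraph oracle
  # must find more components than the gap-free truth
  truth_cc <- igraph_components(ph$truth$voxels > 0)
  obs_cc <- igraph_components(ph$observed$voxels > 0)
  expect_identical(truth_cc$n, 1L)
  expect_gte(obs_cc$n, 2L)
})

test_that("ellipsoidal organ volumes match the analytic value within 10%", {
  ph <- plain_phantom()
  spc <- prod(ph$truth$spacing)
  analytic_kidneys <- 2 * 4 / 3 * pi * prod(ph$spec$kidney_axes)
  analytic_bladder <- 4 / 3 * pi * prod(ph$spec$bladder_axes)
  expect_lt(abs(sum(ph$truth$voxels == 1) * spc - analytic_kidneys) /
              analytic_kidneys, 0.10)
  expect_lt(abs(sum(ph$truth$voxels == 3) * spc - analytic_bladder) /
              analytic_bladder, 0.10)
})

test_that("gap injection removes the requested arc length", {
  len <- 15
  ph <- gapped_phantom()
  removed <- which(ph$truth$voxels == 2L & ph$observed$voxels == 0L)
  mm <- focusctu:::linear_to_mm(ph$truth, removed)
  pl <- focusctu:::polyline_distance(mm, ph$centerlines$left$control)
  span <- diff(range(pl$arc))
  tol <- 2 * max(ph$truth$spacing)
  expect_gt(span, len - tol)
  expect_lt(span, len + tol)
})

test_that("gap-free ureters connect kidney to bladder", {
  ph <- plain_phantom()
  cc <- connected_components(ph$truth$voxels > 0)
  expect_identical(attr(cc, "n_components"), 1L)
})

test_that("invalid specs are rejected with informative errors", {
  spec <- default_spec("small")
  spec$bladder_center <- spec$kidney_centers[[1]] + c(5, 0, 0)
  expect_error(generate_phantom(spec), "left kidney and bladder")

  too_close <- default_spec("small",
    lesions = list(list(center = c(70, 80, 60), radius_mm = 5, hu = 80)))
  expect_error(generate_phantom(too_close), "mm from the urinary tract")
})

test_that("standard scale covers the working field of view", {
  spec <- default_spec("standard")
  expect_equal(spec$dim * spec$spacing, c(192, 160, 256))
  # small fits the fast-test grid
  small <- default_spec("small")
  expect_true(all(small$dim <= c(96, 80, 64)))
})

test_that("phantom output carries the applied misalignment", {
  ph <- generate_phantom(default_spec("small", misalignment = "default"))
  expect_s3_class(ph$misalignment, "affine_transform")
  dev <- focusctu:::transform_deviation(ph$misalignment)
  expect_gt(dev$translation_mm, 0)
  # identical phantom without misalignment differs in the unenhanced only
  ph0 <- generate_phantom(default_spec("small"))
  expect_identical(ph0$ctu$voxels, ph$ctu$voxels)
  expect_false(identical(ph0$unenhanced$voxels, ph$unenhanced$voxels))
})

test_that("perturb_spec varies anatomy deterministically", {
  a <- perturb_spec(default_spec("small"), seed = 3)
  b <- perturb_spec(default_spec("small"), seed = 3)
  c <- perturb_spec(default_spec("small"), seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$kidney_centers, c$kidney_centers))
  expect_s3_class(generate_phantom(a)$truth, "label_volume")
})
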