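test_that("organ_coverage handles full, empty and half masks", {
  ph <- plain_phantom()
  d <- dim(ph$truth$voxels)
  full <- array(TRUE, d)
  none <- array(FALSE, d)
  cov_full <- organ_coverage(ph$truth, full, ph$centerlines)
  cov_none <- organ_coverage(ph$truth, none, ph$centerlines)
  expect_true(all(cov_full$coverage == 1))
  expect_true(all(cov_none$coverage == 0))
  expect_setequal(unique(cov_full$organ), c("kidney", "ureter", "bladder"))
  expect_identical(sum(cov_full$organ == "kidney"), 2L)

  # analytic plane cut through the bladder centre -> coverage ~ 0.5
  centers <- voxel_centers(ph$truth)
  half <- array(centers[, 1] <= ph$spec$bladder_center[1], d)
  cov_half <- organ_coverage(ph$truth, half, ph$centerlines)
  bl <- cov_half[cov_half$organ == "bladder", "coverage"]
  vox_frac <- 1 / (sum(ph$truth$voxels == 3))^(1 / 3)
  expect_lt(abs(bl - 0.5), 0.5 * vox_frac + 0.02)
})

test_that("ureter thirds partition each side's voxels", {
  ph <- plain_phantom()
  cov <- organ_coverage(ph$truth, array(TRUE, dim(ph$truth$voxels)),
                        ph$centerlines, split_ureters = TRUE)
  ur <- cov[cov$organ == "ureter", ]
  expect_setequal(unique(ur$segment), c("proximal", "mid", "distal"))
  expect_setequal(unique(ur$side), c("left", "right"))
  # the sides and thirds together cover every ureter voxel exactly once
  expect_identical(sum(ur$n_voxels), sum(ph$truth$voxels == 2L))
  # the default phantom is left-right symmetric, so sides split evenly
  expect_equal(sum(ur$n_voxels[ur$side == "left"]),
               sum(ur$n_voxels[ur$side == "right"]))
})

test_that("organs without truth voxels report missing coverage", {
  lab <- label_volume(array(0L, c(4, 4, 4)))
  lab$voxels[2, 2, 2] <- 1L
  cov <- organ_coverage(label_volume(lab$voxels), array(TRUE, c(4, 4, 4)))
  expect_true(is.na(cov$coverage[cov$organ == "bladder"]))
  expect_identical(cov$n_voxels[cov$organ == "bladder"], 0L)
})

test_that("4-point score reproduces the published scale anchors", {
  expect_identical(score_4point(1.0), 4L)
  expect_identical(score_4point(0.97), 3L)
  expect_identical(score_4point(0.50), 1L)
  expect_identical(score_4point(0.95), 2L)
  expect_identical(score_4point(0.75), 1L)
  expect_identical(score_4point(0.9999, tau = 0.001), 4L)
  expect_error(score_4point(1.2), "within")
})

test_that("3-point score respects the miniscule threshold", {
  expect_identical(score_3point(1.0), 3L)
  expect_identical(score_3point(0.99), 2L)
  expect_identical(score_3point(0.50), 1L)
  expect_identical(score_3point(0.90, threshold = 0.9), 2L)
  expect_error(score_3point(0.5, threshold = 1.5), "threshold")
})

test_that("visibility scores are monotone in coverage", {
  cov <- sort(runif(200))
  expect_true(all(diff(score_4point(cov)) >= 0))
  expect_true(all(diff(score_3point(cov)) >= 0))
})

test_that("diagnostic metrics handle zero denominators explicitly", {
  m <- diagnostic_metrics(tp = 0, fp = 0, fn = 0, tn = 5)
  expect_identical(m$specificity, 100.0)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_error(diagnostic_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("sensitivity and NPV are both 100 iff FN = 0", {
  set.seed(11)
  for (i in 1:50) {
    tab <- diagnostic_metrics(tp = sample(1:20, 1), fp = sample(0:10, 1),
                              fn = sample(0:10, 1), tn = sample(1:20, 1))
    both100 <- !is.na(tab$sensitivity) && !is.na(tab$npv) &&
      tab$sensitivity == 100 && tab$npv == 100
    expect_identical(both100, tab$fn == 0L)
  }
})

test_that("cohen_kappa matches closed-form arithmetic", {
  # agreement table a=10 (both +), b=2 (+/-), c=3 (-/+), d=5 (both -):
  # po = 15/20; p1+ = 12/20, p2+ = 13/20;
  # pe = 0.6*0.65 + 0.4*0.35 = 0.53; kappa = 0.22/0.47
  r1 <- rep(c(1, 1, 0, 0), c(10, 2, 3, 5))
  r2 <- rep(c(1, 0, 1, 0), c(10, 2, 3, 5))
  expect_equal(cohen_kappa(r1, r2), 0.22 / 0.47, tolerance = 1e-12)
  # perfect agreement
  expect_equal(cohen_kappa(c(1, 0, 1), c(1, 0, 1)), 1.0)
  # symmetry and label invariance
  expect_equal(cohen_kappa(r1, r2), cohen_kappa(r2, r1))
  expect_equal(cohen_kappa(ifelse(r1 == 1, "pos", "neg"),
                           ifelse(r2 == 1, "pos", "neg")),
               cohen_kappa(r1, r2))
  expect_error(cohen_kappa(1:3, 1:4), "equal length")
  expect_warning(k <- cohen_kappa(rep(1, 5), rep(1, 5)), "undefined")
  expect_true(is.na(k))
})

test_that("kappa of independent raters is near zero (Monte-Carlo null)", {
  set.seed(202)
  r1 <- rbinom(10000, 1, 0.4)
  r2 <- rbinom(10000, 1, 0.6)
  expect_lt(abs(cohen_kappa(r1, r2)), 0.05)
})

test_that("concealment_check quantifies lesion hiding", {
  inc <- array(FALSE, c(5, 5, 5))
  inc[1:2, 1, 1] <- TRUE
  mask <- array(FALSE, c(5, 5, 5))
  expect_identical(concealment_check(inc, mask),
                   list(hidden_fraction = 1.0, all_hidden = TRUE))
  mask[1:2, 1, 1] <- TRUE
  expect_identical(concealment_check(inc, mask),
                   list(hidden_fraction = 0.0, all_hidden = FALSE))
  mask[2, 1, 1] <- FALSE
  res <- concealment_check(inc, mask)
  expect_equal(res$hidden_fraction, 0.5)
  expect_false(res$all_hidden)
  expect_warning(res0 <- concealment_check(array(FALSE, c(5, 5, 5)), mask),
                 "empty")
  expect_true(res0$all_hidden)
})

test_that("visibility reporting follows the table conventions", {
  counts <- data.frame(
    organ = c("kidneys", "ureters", "bladder"),
    complete = c(76, 63, 37),
    substantial = c(2, 12, 1),
    miniscule = c(0, 3, 1))
  out <- summarize_visibility(counts)
  expect_equal(out$complete_pct, c(97.4, 80.8, 94.8))
  expect_equal(out$complete_pct + out$substantial_pct + out$miniscule_pct,
               rep(100, 3))
  expect_equal(case_rate_pct(26, 39), 66.6)
  expect_equal(case_rate_pct(57, 60), 95.0)
})
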