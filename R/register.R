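#' Cross-correlation between two volumes
#'
#' Pearson correlation of voxel intensities over an overlap region.
#'
#' @param a,b volumes on the same grid.
#' @param overlap optional logical array selecting the voxels to compare
#'   (default: all).
#' @return Scalar in `[-1, 1]`.
#' @export
cross_correlation <- function(a, b, overlap = NULL) {
  stop_if_grid_mismatch(a, b)
  va <- as.numeric(a$voxels)
  vb <- as.numeric(b$voxels)
  if (!is.null(overlap)) {
    sel <- as.logical(overlap)
    if (!any(sel)) stop("overlap mask is empty")
    va <- va[sel]
    vb <- vb[sel]
  }
  if (sd(va) == 0 || sd(vb) == 0)
    stop("cross-correlation undefined: constant image within overlap")
  cor(va, vb)
}

# separable (1,2,1)/4 smoothing of an image volume, clamped borders
smooth121 <- function(vol) {
  a <- vol$voxels
  d <- dim(a)
  for (ax in 1:3) {
    if (d[ax] < 2) next
    idx_lo <- c(1L, seq_len(d[ax] - 1L))
    idx_hi <- c(seq_len(d[ax] - 1L) + 1L, d[ax])
    pick <- function(i) switch(ax, a[i, , , drop = FALSE],
                               a[, i, , drop = FALSE],
                               a[, , i, drop = FALSE])
    a <- 0.5 * a + 0.25 * pick(idx_lo) + 0.25 * pick(idx_hi)
  }
  image_volume(a, vol$spacing, vol$origin)
}

# metric for the optimizer: NCC between fixed and the moving volume pulled
# back through the current transform. Evaluated over a FIXED interior
# region (the fixed grid inset by margin_mm): a sample set that varies
# with the transform makes the metric discontinuous (border voxels drop
# in and out of the overlap), which defeats line searches. Out-of-field
# samples take the air fill value.
ncc_metric <- function(fixed, moving, transform, region = NULL,
                       margin_mm = 20) {
  inv <- invert_transform(transform)
  res <- resample_onto(moving, grid_of(fixed), A = inv$matrix,
                       tr = inv$translation, fill = -1024)
  if (is.null(region)) region <- interior_region(fixed, margin_mm)
  va <- as.numeric(fixed$voxels)[region]
  vb <- as.numeric(res$voxels)[region]
  if (length(va) < 32) return(-1)
  if (sd(va) == 0 || sd(vb) == 0) return(NA_real_)
  cor(va, vb)
}

# linear indices of the fixed grid inset by margin_mm per axis (at least
# one interior voxel per axis is kept)
interior_region <- function(volume, margin_mm) {
  d <- dim(volume$voxels)
  ins <- pmin(ceiling(margin_mm / volume$spacing), (d - 1) %/% 2)
  keep <- Map(function(n, i) (1 + i):(n - i), d, ins)
  arr <- array(FALSE, d)
  arr[keep[[1]], keep[[2]], keep[[3]]] <- TRUE
  which(arr)
}

params_to_transform <- function(theta, model, center, lever) {
  if (model == "rigid") {
    rigid_transform(angles_deg = theta[1:3], translation = theta[4:6],
                    center = center)
  } else {
    M <- diag(3) + matrix(theta[1:9] / lever, 3, 3)
    t_eff <- theta[10:12]
    # parameterize about the volume centre so matrix and translation
    # parameters are comparably scaled (~1 unit ~ 1 mm at the centre)
    affine_transform(M, as.numeric(center + t_eff - M %*% center))
  }
}

#' Register the unenhanced scan onto the CTU frame
#'
#' Estimates the affine (or rigid) transform mapping moving-frame physical
#' points into the fixed frame by maximizing the cross-correlation between
#' the fixed volume and the pulled-back moving volume. Optimization is
#' gradient-based (quasi-Newton with finite-difference gradients on scaled
#' parameters), seeded from the identity, over a coarse-to-fine image
#' pyramid. Deterministic given its options.
#'
#' @param fixed,moving nonconstant [image_volume()] objects.
#' @param model `"affine"` (default) or `"rigid"`.
#' @param pyramid integer vector of downsampling factors, coarse to fine.
#' @param maxit maximum optimizer iterations per pyramid level (recycled
#'   along the pyramid).
#' @param smooth number of light (1,2,1)/4 separable smoothing passes
#'   applied to both volumes at every level before metric evaluation;
#'   reduces the interpolation-blur bias of the metric near edges.
#' @param margin_mm inset of the fixed-image metric region: the metric is
#'   sampled on a fixed interior set so its value stays continuous in the
#'   transform; should exceed the largest expected displacement.
#' @param tol relative metric tolerance for convergence.
#' @return An [affine_transform()] with attributes `metric` (final NCC),
#'   `metric_identity` (NCC at identity) and `iterations`.
#' @export
register <- function(fixed, moving, model = c("affine", "rigid"),
                     pyramid = c(4, 2, 1), maxit = c(100, 40, 15),
                     smooth = 1, margin_mm = 20, tol = 1e-8) {
  model <- match.arg(model)
  if (sd(fixed$voxels) == 0 || sd(moving$voxels) == 0)
    stop("registration undefined for constant volumes")
  d <- dim(fixed$voxels)
  center <- fixed$origin + (d - 1) * fixed$spacing / 2
  lever <- max((d - 1) * fixed$spacing) / 2
  maxit <- rep_len(maxit, length(pyramid))

  level_volumes <- function(vol, f) {
    v <- vol
    for (i in seq_len(smooth)) v <- smooth121(v)
    if (f == 1) return(v)
    # antialias before coarse sampling: one extra smoothing pass per
    # halving of resolution
    for (i in seq_len(round(log2(f)))) v <- smooth121(v)
    resample(v, vol$spacing * f)
  }

  theta <- rep(0, if (model == "rigid") 6 else 12)
  iterations <- 0L
  for (lev in seq_along(pyramid)) {
    f <- pyramid[lev]
    fx <- level_volumes(fixed, f)
    mv <- level_volumes(moving, f)
    reg <- interior_region(fx, margin_mm)
    obj <- function(th) {
      tr <- params_to_transform(th, model, center, lever)
      m <- ncc_metric(fx, mv, tr, region = reg)
      if (is.na(m)) return(1)  # constant region: poor score, keep going
      -m
    }
    # central-difference step 0.1 in scaled units (~0.1 mm displacement):
    # large enough for a clean gradient signal on a smooth metric
    fit <- optim(theta, obj, method = "BFGS",
                 control = list(maxit = maxit[lev], reltol = tol,
                                ndeps = rep(0.1, length(theta))))
    theta <- fit$par
    iterations <- iterations + fit$counts[["function"]]
  }
  out <- params_to_transform(theta, model, center, lever)
  attr(out, "metric") <- ncc_metric(fixed, moving, out)
  attr(out, "metric_identity") <- ncc_metric(fixed, moving,
                                             affine_transform())
  attr(out, "iterations") <- iterations
  out
}
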