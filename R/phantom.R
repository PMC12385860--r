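#' Phantom specification
#'
#' Describes a synthetic abdomen used to exercise the focused-view
#' pipeline: two ellipsoidal kidneys, two tubular ureters following
#' polyline centrelines, one ellipsoidal bladder, an elliptic-cylinder
#' "body" surrounded by air, optional unopacified ureter gaps, optional
#' extra-tract incidental lesions, additive Gaussian noise, and a known
#' misalignment between the paired CTU and unenhanced volumes.
#'
#' All geometry is in physical mm. The ureter tube is the set of points
#' within `ureter_radius_mm` of the centreline polyline; a gap is an
#' arc-length interval `[start_fraction * L, start_fraction * L + length_mm)`
#' whose voxels are removed from the *observed* (but not the truth) labels,
#' emulating ureter segments the contrast never opacified.
#'
#' @param dim grid dimensions (voxels).
#' @param spacing voxel spacing (mm).
#' @param kidney_centers list of two mm centres (left, right).
#' @param kidney_axes semi-axes (mm) shared by both kidneys.
#' @param bladder_center,bladder_axes bladder ellipsoid (mm).
#' @param ureter_controls list with elements `left`/`right`: control-point
#'   matrices (rows = points, mm) from kidney into bladder.
#' @param ureter_radius_mm tube radius (mm).
#' @param body_axes semi-axes (mm) of the elliptic body outline (x, y).
#' @param body_taper two amplitudes of a smooth cranio-caudal modulation
#'   of the body outline (torso taper). A constant-profile cylinder would
#'   leave the cranio-caudal alignment of the paired scans undetermined;
#'   real trunks are not z-uniform. Set `c(0, 0)` for a straight cylinder.
#' @param gaps list of `list(side, start_fraction, length_mm)`.
#' @param lesions list of `list(center, radius_mm, hu)`.
#' @param texture_amp_hu amplitude (HU) of a smooth deterministic
#'   soft-tissue texture added inside the body. Real parenchyma is not
#'   uniform; this low-frequency modulation gives intensity gradients
#'   everywhere, which cross-correlation registration needs. Set 0 for
#'   piecewise-constant output.
#' @param contrast_hu HU of the opacified tract on CTU (fixture constant).
#' @param background_hu soft-tissue HU.
#' @param unopacified_hu HU of tract without contrast (gaps; unenhanced).
#' @param air_hu HU outside the body.
#' @param noise_sd additive Gaussian noise standard deviation (HU).
#' @param misalignment an [affine_transform()]: the moving-to-fixed map
#'   that aligns the unenhanced scan back onto the CTU frame (i.e. exactly
#'   what [register()] should recover).
#' @param seed integer RNG seed.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(dim, spacing, kidney_centers, kidney_axes,
                         bladder_center, bladder_axes, ureter_controls,
                         ureter_radius_mm = 4, body_axes = c(88, 72),
                         body_taper = c(0.08, 0.05),
                         gaps = list(), lesions = list(),
                         texture_amp_hu = 15,
                         contrast_hu = 300, background_hu = 40,
                         unopacified_hu = 35, air_hu = -1024,
                         noise_sd = 10, misalignment = NULL, seed = 1L) {
  if (is.null(misalignment)) misalignment <- affine_transform()
  spec <- list(dim = as.integer(dim), spacing = check_spacing(spacing),
               kidney_centers = lapply(kidney_centers, as.numeric),
               kidney_axes = as.numeric(kidney_axes),
               bladder_center = as.numeric(bladder_center),
               bladder_axes = as.numeric(bladder_axes),
               ureter_controls = lapply(ureter_controls, as.matrix),
               ureter_radius_mm = as.numeric(ureter_radius_mm),
               body_axes = as.numeric(body_axes),
               body_taper = as.numeric(body_taper),
               gaps = gaps, lesions = lesions,
               texture_amp_hu = texture_amp_hu,
               contrast_hu = contrast_hu, background_hu = background_hu,
               unopacified_hu = unopacified_hu, air_hu = air_hu,
               noise_sd = noise_sd, misalignment = misalignment,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

#' Default phantom specifications
#'
#' `"small"` fits a 96 x 80 x 64 grid at 2 mm isotropic spacing (field of
#' view 192 x 160 x 128 mm), sized for fast tests; `"standard"` uses a
#' 192 x 160 x 128 grid at 1 x 1 x 2 mm spacing, i.e. a field of view of
#' 192 x 160 x 256 mm. Repeated calls with the same arguments return
#' identical specs.
#'
#' @param scale `"small"` or `"standard"`.
#' @param seed RNG seed stored in the spec.
#' @param gaps,lesions,noise_sd,misalignment optional overrides; see
#'   [phantom_spec()]. `misalignment = "default"` installs a small rigid
#'   misalignment (3, -2, 4) mm translation plus 2 degrees about z.
#' @return A `phantom_spec`.
#' @export
default_spec <- function(scale = c("small", "standard"), seed = 1L,
                         gaps = list(), lesions = list(),
                         noise_sd = 10, misalignment = NULL) {
  scale <- match.arg(scale)
  zf <- if (scale == "small") 1 else 2   # z stretch relative to 128 mm FOV
  dm <- if (scale == "small") c(96L, 80L, 64L) else c(192L, 160L, 128L)
  sp <- if (scale == "small") c(2, 2, 2) else c(1, 1, 2)
  ctrl_left <- rbind(c(48, 80, 38), c(56, 76, 60), c(64, 82, 80),
                     c(80, 80, 96), c(90, 80, 100))
  ctrl_left[, 3] <- ctrl_left[, 3] * zf
  ctrl_right <- ctrl_left
  ctrl_right[, 1] <- 192 - ctrl_right[, 1]
  center <- (dm - 1) * sp / 2
  if (identical(misalignment, "default"))
    misalignment <- rigid_transform(c(0, 0, 2), c(3, -2, 4), center = center)
  phantom_spec(dim = dm, spacing = sp,
               kidney_centers = list(c(48, 80, 26 * zf), c(144, 80, 26 * zf)),
               kidney_axes = c(15, 13, 20 * zf),
               bladder_center = c(96, 80, 104 * zf),
               bladder_axes = c(24, 21, 16 * zf),
               ureter_controls = list(left = ctrl_left, right = ctrl_right),
               ureter_radius_mm = 4,
               gaps = gaps, lesions = lesions, noise_sd = noise_sd,
               misalignment = misalignment, seed = seed)
}

#' Randomly perturb a phantom's anatomy
#'
#' Jitters organ centres, semi-axes and ureter control points by seeded
#' Gaussian offsets, producing anatomically varied phantoms for training
#' and property tests. The body outline, HU palette and grid are kept.
#'
#' @param spec a `phantom_spec`.
#' @param seed integer seed for the jitter (also stored in the result).
#' @param sd_mm standard deviation of the positional jitter (mm).
#' @return A new `phantom_spec`.
#' @export
perturb_spec <- function(spec, seed, sd_mm = 3) {
  with_seed(seed, {
    jit <- function(x, s = sd_mm) x + rnorm(length(x), 0, s)
    spec$kidney_centers <- lapply(spec$kidney_centers, jit, s = sd_mm)
    spec$kidney_axes <- pmax(8, jit(spec$kidney_axes, sd_mm / 2))
    spec$bladder_center <- jit(spec$bladder_center)
    spec$bladder_axes <- pmax(10, jit(spec$bladder_axes, sd_mm / 2))
    spec$ureter_controls <- lapply(spec$ureter_controls, function(m) {
      m + matrix(rnorm(length(m), 0, sd_mm / 2), nrow(m), ncol(m))
    })
    spec$seed <- as.integer(seed)
    spec
  })
}

# run code with a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# smooth deterministic soft-tissue texture, evaluated at mm points; moves
# with the anatomy because the unenhanced volume evaluates it at the
# misaligned points
texture_field <- function(P) {
  sin(2 * pi * P[, 1] / 47 + 1) * sin(2 * pi * P[, 2] / 61 + 2) +
    sin(2 * pi * (P[, 1] + 2 * P[, 2] + 3 * P[, 3]) / 83) *
      cos(2 * pi * P[, 3] / 53)
}

# distance from points P (n x 3 mm) to a polyline, plus arc-length position
# of the closest point. Vectorized over segments.
polyline_distance <- function(P, control) {
  n <- nrow(P)
  seg_len <- sqrt(rowSums((control[-1, , drop = FALSE] -
                           control[-nrow(control), , drop = FALSE])^2))
  cum0 <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, n)
  best_s <- numeric(n)
  for (j in seq_len(nrow(control) - 1)) {
    a <- control[j, ]
    b <- control[j + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    pa <- sweep(P, 2, a, "-")
    t <- pmin(1, pmax(0, as.numeric(pa %*% ab) / len2))
    diff <- pa - outer(t, ab)
    d2 <- rowSums(diff^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- cum0[j] + t[upd] * seg_len[j]
  }
  list(distance = sqrt(best_d2), arc = best_s, total = cum0[length(cum0)])
}

# evaluate the noise-free anatomy at arbitrary mm points; returns a list of
# logical membership vectors
phantom_membership <- function(spec, P) {
  inside_ellipsoid <- function(center, axes) {
    q <- sweep(P, 2, center, "-")
    q <- sweep(q, 2, axes, "/")
    rowSums(q^2) <= 1
  }
  body_c <- c((spec$dim[1] - 1) * spec$spacing[1] / 2,
              (spec$dim[2] - 1) * spec$spacing[2] / 2)
  lz <- (spec$dim[3] - 1) * spec$spacing[3]
  tap <- spec$body_taper %||% c(0, 0)
  # taper terms are <= 0 so the outline never exceeds body_axes and the
  # air border survives at every slice; tap = c(0, 0) gives a cylinder
  s <- 1 + tap[1] * (sin(pi * P[, 3] / lz + 0.4) - 1) +
    tap[2] * (sin(2 * pi * P[, 3] / lz + 1) - 1)
  bq <- cbind((P[, 1] - body_c[1]) / (spec$body_axes[1] * s),
              (P[, 2] - body_c[2]) / (spec$body_axes[2] * s))
  body <- rowSums(bq^2) <= 1
  kidneys <- inside_ellipsoid(spec$kidney_centers[[1]], spec$kidney_axes) |
    inside_ellipsoid(spec$kidney_centers[[2]], spec$kidney_axes)
  bladder <- inside_ellipsoid(spec$bladder_center, spec$bladder_axes)
  ur <- lapply(spec$ureter_controls, function(ctrl)
    polyline_distance(P, ctrl))
  ureter_in <- lapply(ur, function(u) u$distance <= spec$ureter_radius_mm)
  lesion <- rep(FALSE, nrow(P))
  for (l in spec$lesions) {
    q <- sweep(P, 2, l$center, "-")
    lesion <- lesion | rowSums(q^2) <= l$radius_mm^2
  }
  list(body = body, kidneys = kidneys, bladder = bladder,
       ureter = ureter_in, ureter_info = ur, lesion = lesion)
}

# is a ureter arc position inside one of that side's gaps?
in_gap <- function(arc, total, gaps, side) {
  hit <- rep(FALSE, length(arc))
  for (g in gaps) {
    if (!identical(g$side, side)) next
    s0 <- g$start_fraction * total
    hit <- hit | (arc >= s0 & arc < s0 + g$length_mm)
  }
  hit
}

#' Generate a synthetic paired CTU / unenhanced phantom
#'
#' Renders the spec's analytic anatomy onto the voxel grid (a voxel is
#' labelled iff its centre lies inside the shape; label precedence
#' kidney > bladder > ureter where shapes meet) and produces:
#' \describe{
#'   \item{ctu}{contrast-enhanced volume: opacified tract at
#'     `contrast_hu`, gap segments at `unopacified_hu`, plus noise.}
#'   \item{unenhanced}{the same anatomy without contrast, rendered through
#'     the spec's misalignment with independent noise.}
#'   \item{truth}{gap-free labels.}
#'   \item{observed}{labels with gap voxels removed from the ureters (what
#'     a segmenter of opacified tract could see).}
#'   \item{incidental_mask}{logical array of lesion voxels.}
#'   \item{misalignment}{the applied [affine_transform()] (moving-to-fixed
#'     convention; see [phantom_spec()]).}
#'   \item{centerlines}{per-side ureter centreline control points and total
#'     arc length, for arc-fraction organ splitting.}
#' }
#' Output is deterministic given the spec (which includes the seed).
#'
#' @param spec a `phantom_spec`.
#' @return A `phantom_output` list as described above.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  d <- spec$dim
  n <- prod(d)
  vol0 <- image_volume(array(0, dim = d), spec$spacing, c(0, 0, 0))
  P <- voxel_centers(vol0)

  mem <- phantom_membership(spec, P)
  sides <- names(spec$ureter_controls)
  gap_hit <- lapply(sides, function(s) {
    u <- mem$ureter_info[[s]]
    mem$ureter[[s]] & in_gap(u$arc, u$total, spec$gaps, s)
  })
  names(gap_hit) <- sides
  ureter_any <- Reduce(`|`, mem$ureter)
  ureter_obs <- Reduce(`|`, Map(function(m, g) m & !g, mem$ureter, gap_hit))

  codes <- label_codes()
  truth <- integer(n)
  truth[ureter_any] <- codes[["ureter"]]
  truth[mem$bladder] <- codes[["bladder"]]
  truth[mem$kidneys] <- codes[["kidney"]]
  observed <- integer(n)
  observed[ureter_obs] <- codes[["ureter"]]
  observed[mem$bladder] <- codes[["bladder"]]
  observed[mem$kidneys] <- codes[["kidney"]]

  validate_lesion_clearance(spec, truth, d)

  render <- function(m, pts, contrast) {
    hu <- rep(spec$air_hu, nrow(pts))
    hu[m$body] <- spec$background_hu
    tract <- m$kidneys | m$bladder | Reduce(`|`, m$ureter)
    hu[tract] <- spec$unopacified_hu
    if (contrast) hu[mem$kidneys | mem$bladder | ureter_obs] <- spec$contrast_hu
    for (l in spec$lesions) {
      q <- sweep(pts, 2, l$center, "-")
      hu[rowSums(q^2) <= l$radius_mm^2] <- l$hu %||% 80
    }
    amp <- spec$texture_amp_hu %||% 0
    if (amp > 0) hu[m$body] <- hu[m$body] + amp * texture_field(pts)[m$body]
    hu
  }

  ctu_hu <- render(mem, P, contrast = TRUE)

  # unenhanced: evaluate the anatomy at misaligned points, no contrast.
  # unenhanced(q) = anatomy(M(q)) makes the stored M the moving-to-fixed
  # map that registration must recover.
  Pm <- transform_points(spec$misalignment, P)
  mem_m <- phantom_membership(spec, Pm)
  unenh_hu <- render(mem_m, Pm, contrast = FALSE)

  noise <- with_seed(spec$seed, list(ctu = rnorm(n, 0, spec$noise_sd),
                                     unenh = rnorm(n, 0, spec$noise_sd)))
  ctu <- image_volume(array(ctu_hu + noise$ctu, dim = d), spec$spacing)
  unenhanced <- image_volume(array(unenh_hu + noise$unenh, dim = d),
                             spec$spacing)

  centerlines <- lapply(sides, function(s)
    list(control = spec$ureter_controls[[s]],
         total = mem$ureter_info[[s]]$total))
  names(centerlines) <- sides

  structure(list(
    ctu = ctu, unenhanced = unenhanced,
    truth = label_volume(array(as.integer(truth), dim = d), spec$spacing),
    observed = label_volume(array(as.integer(observed), dim = d),
                            spec$spacing),
    incidental_mask = array(mem$lesion, dim = d),
    misalignment = spec$misalignment,
    centerlines = centerlines, spec = spec), class = "phantom_output")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_phantom_spec <- function(spec) {
  pairs <- list(
    list("left kidney", "right kidney",
         spec$kidney_centers[[1]], spec$kidney_axes,
         spec$kidney_centers[[2]], spec$kidney_axes),
    list("left kidney", "bladder",
         spec$kidney_centers[[1]], spec$kidney_axes,
         spec$bladder_center, spec$bladder_axes),
    list("right kidney", "bladder",
         spec$kidney_centers[[2]], spec$kidney_axes,
         spec$bladder_center, spec$bladder_axes))
  for (p in pairs) {
    # conservative analytic separation test for two ellipsoids: centres
    # further apart than the sum of the largest semi-axes cannot collide;
    # otherwise sample the straight line between centres
    gapv <- p[[5]] - p[[3]]
    dist <- sqrt(sum(gapv^2))
    if (dist > max(p[[4]]) + max(p[[6]])) next
    ts <- seq(0, 1, length.out = 200)
    pts <- outer(ts, gapv) + matrix(p[[3]], length(ts), 3, byrow = TRUE)
    in1 <- rowSums(sweep(sweep(pts, 2, p[[3]], "-"), 2, p[[4]], "/")^2) <= 1
    in2 <- rowSums(sweep(sweep(pts, 2, p[[5]], "-"), 2, p[[6]], "/")^2) <= 1
    if (any(in1 & in2))
      stop("overlapping organ specification: ", p[[1]], " and ", p[[2]])
  }
  for (g in spec$gaps) {
    stopifnot(g$side %in% names(spec$ureter_controls),
              g$start_fraction >= 0, g$start_fraction < 1, g$length_mm > 0)
  }
  invisible(TRUE)
}

# every lesion centre must keep (boundary + bridge) clearance from the
# tract plus its own radius, so method-3 concealment is well-posed
validate_lesion_clearance <- function(spec, truth, d,
                                      clearance_mm = 30) {
  if (length(spec$lesions) == 0) return(invisible(TRUE))
  tract <- array(truth > 0, dim = d)
  dist <- distance_to_mask(tract, spec$spacing)
  vol <- image_volume(array(0, dim = d), spec$spacing)
  for (l in spec$lesions) {
    idx <- round((l$center - vol$origin) / vol$spacing) + 1
    idx <- pmin(pmax(idx, 1), d)
    dmin <- dist[idx[1], idx[2], idx[3]]
    if (dmin < clearance_mm + l$radius_mm)
      stop("incidental lesion at (", paste(l$center, collapse = ", "),
           ") is only ", round(dmin, 1), " mm from the urinary tract; ",
           "need >= ", clearance_mm + l$radius_mm, " mm")
  }
  invisible(TRUE)
}
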