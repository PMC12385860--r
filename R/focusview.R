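#' Focused-view configuration
#'
#' @param method masking method: 1 = raw segmentation, 2 = segmentation
#'   dilated by a spherical `boundary_mm` margin, 3 = method 2 plus
#'   straight-path bridging of disconnected tract components with the
#'   bridge paths dilated by `bridge_radius_mm`.
#' @param boundary_mm safety boundary around the segmented tract (mm).
#' @param bridge_radius_mm dilation radius applied to bridge paths (mm).
#' @param fill_hu value written outside the mask (default -1024, air).
#' @param connectivity component connectivity (6, 18 or 26).
#' @return A `focused_view_config` object.
#' @export
focused_view_config <- function(method = 3, boundary_mm = 10,
                                bridge_radius_mm = 20, fill_hu = -1024,
                                connectivity = 26) {
  stopifnot(method %in% 1:3, boundary_mm >= 0, bridge_radius_mm >= 0,
            connectivity %in% c(6, 18, 26))
  structure(list(method = as.integer(method), boundary_mm = boundary_mm,
                 bridge_radius_mm = bridge_radius_mm, fill_hu = fill_hu,
                 connectivity = as.integer(connectivity)),
            class = "focused_view_config")
}

#' Method 1: mask equal to the raw segmentation
#'
#' @param labels a [label_volume()].
#' @return Logical 3-D array, `TRUE` where the label is nonzero.
#' @export
method1_mask <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  array(labels$voxels > 0L, dim = dim(labels$voxels))
}

#' Method 2: segmentation with a spherical boundary
#'
#' Dilates the method-1 mask by `boundary_mm` with a spherical structuring
#' element in physical mm (see [dilate_mm()]).
#'
#' @param labels a [label_volume()].
#' @param boundary_mm boundary radius (mm), `>= 0`.
#' @return Logical 3-D array.
#' @export
method2_mask <- function(labels, boundary_mm = 10) {
  dilate_mm(method1_mask(labels), boundary_mm, labels$spacing)
}

#' Bridge disconnected tract components with straight paths
#'
#' Runs connected-component analysis on the union of all urinary-tract
#' labels. While more than one component remains, selects a disconnected
#' component containing ureter voxels (tie-break: smallest voxel count,
#' then lowest lexicographic centroid), finds the closest voxel-centre pair
#' between it and the nearest other component (Euclidean mm, via the
#' components' surface voxels), rasterizes a straight voxel path between
#' the pair, and merges. If no remaining disconnected component contains
#' ureter voxels (e.g. labels without ureters), the smallest component is
#' bridged instead, with a warning when kidneys or bladder are absent.
#'
#' @param labels a [label_volume()].
#' @param config a [focused_view_config()].
#' @return List with `mask` (logical array: tract plus bridge paths,
#'   one connected component) and `bridges` (list of segments, each with
#'   mm endpoints `from`/`to` and `length_mm`).
#' @export
bridge_components <- function(labels, config = focused_view_config()) {
  stopifnot(inherits(labels, "label_volume"))
  lab_arr <- labels$voxels
  tract <- lab_arr > 0L
  if (!any(tract)) stop("labels contain no urinary-tract voxels")
  codes <- label_codes()
  if (!any(lab_arr == codes[["kidney"]]) || !any(lab_arr == codes[["bladder"]]))
    warning("labels lack kidney or bladder voxels; ",
            "bridging remaining components best-effort")

  bridges <- list()
  repeat {
    comp <- connected_components(tract, config$connectivity)
    k <- attr(comp, "n_components")
    if (k <= 1L) break
    stats <- component_stats(comp, k, lab_arr, codes[["ureter"]],
                             labels)
    cand <- which(stats$has_ureter)
    if (length(cand) == 0) cand <- seq_len(k)
    ord <- order(stats$size[cand],
                 stats$centroid[cand, 1], stats$centroid[cand, 2],
                 stats$centroid[cand, 3])
    pick <- cand[ord[1]]

    surf <- surface_voxels(tract)
    lin_all <- which(surf)
    comp_of <- comp[lin_all]
    lin_a <- lin_all[comp_of == pick]
    # nearest other component by minimal surface-to-surface distance
    best <- NULL
    for (other in setdiff(seq_len(k), pick)) {
      lin_b <- lin_all[comp_of == other]
      np <- nearest_pair_mm(labels, lin_a, lin_b)
      if (is.null(best) || np$distance < best$distance) best <- np
    }
    path <- segment_voxels(labels, best$p_a, best$p_b)
    tract[path] <- TRUE
    bridges[[length(bridges) + 1L]] <-
      list(from = as.numeric(best$p_a), to = as.numeric(best$p_b),
           length_mm = best$distance)
  }
  list(mask = tract, bridges = bridges)
}

component_stats <- function(comp, k, lab_arr, ureter_code, volume) {
  size <- tabulate(comp[comp > 0L], nbins = k)
  has_ureter <- logical(k)
  centroid <- matrix(NA_real_, k, 3)
  idx <- which(comp > 0L)
  cid <- comp[idx]
  has <- unique(cid[lab_arr[idx] == ureter_code])
  has_ureter[has] <- TRUE
  mm <- linear_to_mm(volume, idx)
  for (c in 1:3) centroid[, c] <- tapply(mm[, c], cid, mean)[as.character(1:k)]
  list(size = size, has_ureter = has_ureter, centroid = centroid)
}

#' Method 3: boundary plus ureter-gap bridging
#'
#' The method-2 mask unioned with every bridge path dilated by
#' `bridge_radius_mm` (the bridge dilation is independent of the boundary
#' dilation; radii do not stack). A constructive superset of method 2.
#'
#' @param labels a [label_volume()].
#' @param config a [focused_view_config()].
#' @return Logical 3-D array, with attribute `bridges` as in
#'   [bridge_components()].
#' @export
method3_mask <- function(labels, config = focused_view_config()) {
  m2 <- method2_mask(labels, config$boundary_mm)
  br <- bridge_components(labels, config)
  if (length(br$bridges) > 0) {
    path_only <- br$mask & !(labels$voxels > 0L)
    m2 <- m2 | dilate_mm(path_only, config$bridge_radius_mm, labels$spacing)
  }
  attr(m2, "bridges") <- br$bridges
  m2
}

#' Apply a binary mask to a volume
#'
#' Voxels inside the mask are copied exactly; voxels outside are replaced
#' by `fill_hu`. Idempotent.
#'
#' @param volume an [image_volume()].
#' @param mask logical array on the same grid.
#' @param fill_hu replacement value (HU).
#' @return A masked `image_volume`.
#' @export
apply_mask <- function(volume, mask, fill_hu = -1024) {
  stopifnot(inherits(volume, "image_volume"))
  if (!identical(dim(mask), dim(volume$voxels)))
    stop("mask grid does not match volume grid")
  out <- volume$voxels
  out[!mask] <- fill_hu
  image_volume(out, volume$spacing, volume$origin)
}

#' Generate a focused view of a paired CTU / unenhanced study
#'
#' Computes the configured method mask from the segmentation (in the CTU
#' frame), registers the unenhanced scan onto the CTU
#' (see [register()]; skipped when `registration = "identity"`), resamples
#' it onto the CTU grid, and masks both volumes. Fully automatic.
#'
#' @param ctu contrast-enhanced [image_volume()].
#' @param unenhanced companion unenhanced [image_volume()] (may be
#'   misaligned with the CTU).
#' @param labels urinary-tract [label_volume()] aligned with the CTU.
#' @param config a [focused_view_config()].
#' @param registration `"rigid"` (default: the pipeline applies rigid
#'   registration before masking), `"affine"` or `"identity"` (skip).
#' @param register_options options passed to [register()].
#' @return A `focused_view_result`: `mask`, `masked_ctu`,
#'   `masked_unenhanced`, `bridges`, `transform`, `config`.
#' @export
focused_view <- function(ctu, unenhanced, labels,
                         config = focused_view_config(),
                         registration = c("rigid", "affine", "identity"),
                         register_options = list()) {
  registration <- match.arg(registration)
  stop_if_grid_mismatch(ctu, labels, "ctu and labels")
  mask <- switch(config$method,
                 method1_mask(labels),
                 method2_mask(labels, config$boundary_mm),
                 method3_mask(labels, config))
  bridges <- attr(mask, "bridges") %||% list()
  if (registration == "identity") {
    transform <- affine_transform()
  } else {
    opts <- modifyList(list(model = registration), register_options)
    transform <- do.call(register, c(list(fixed = ctu, moving = unenhanced),
                                     opts))
  }
  moved <- apply_transform(unenhanced, transform, ctu,
                           fill = config$fill_hu)
  structure(list(
    mask = array(as.logical(mask), dim = dim(mask)),
    masked_ctu = apply_mask(ctu, mask, config$fill_hu),
    masked_unenhanced = apply_mask(moved, mask, config$fill_hu),
    bridges = bridges, transform = transform, config = config),
    class = "focused_view_result")
}
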