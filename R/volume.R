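#' @useDynLib focusctu, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor optim rnorm runif sd setNames
#' @importFrom utils modifyList
NULL

#' Construct a CT image volume
#'
#' An `image_volume` is a 3-D scalar grid of Hounsfield units (HU) together
#' with its voxel spacing and origin. Voxel indexing is 1-based in R; the
#' physical centre of voxel `(i, j, k)` is
#' `origin + ((i - 1) * sx, (j - 1) * sy, (k - 1) * sz)` mm. Axis order is
#' fixed as (x, y, z) with z the cranio-caudal axis.
#'
#' @param voxels 3-D numeric array of intensities (HU).
#' @param spacing numeric length-3, voxel spacing in mm, all `> 0`.
#' @param origin numeric length-3, physical position (mm) of voxel (1,1,1).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as_array3d(voxels)
  spacing <- check_spacing(spacing)
  origin <- check_origin(origin)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = c("image_volume", "ct_volume"))
}

#' Construct a label volume
#'
#' A `label_volume` shares the grid conventions of [image_volume()] but
#' holds integer class codes: 0 background, 1 kidney, 2 ureter, 3 bladder.
#'
#' @param labels 3-D integer array with values in `{0, 1, 2, 3}`.
#' @inheritParams image_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  labels <- as_array3d(labels)
  if (!all(labels %in% 0:3)) {
    bad <- setdiff(unique(as.vector(labels)), 0:3)
    stop("label values must be in {0,1,2,3}; found ",
         paste(bad, collapse = ", "))
  }
  storage.mode(labels) <- "integer"
  spacing <- check_spacing(spacing)
  origin <- check_origin(origin)
  structure(list(voxels = labels, spacing = spacing, origin = origin),
            class = c("label_volume", "ct_volume"))
}

#' Class codes used by label volumes
#' @return Named integer vector mapping organ names to label codes.
#' @export
label_codes <- function() {
  c(background = 0L, kidney = 1L, ureter = 2L, bladder = 3L)
}

as_array3d <- function(x) {
  if (is.null(dim(x))) stop("voxel data must be a 3-D array, got a vector")
  if (length(dim(x)) != 3L)
    stop("voxel data must have rank 3, got rank ", length(dim(x)))
  if (any(dim(x) < 1L)) stop("every dimension must be >= 1")
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  x
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers (mm)")
  spacing
}

check_origin <- function(origin) {
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers (mm)")
  origin
}

#' @export
print.ct_volume <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label_volume" else "image_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n", kind,
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  rng <- range(x$voxels)
  cat(sprintf("  value range [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Check that two volumes share the same grid
#'
#' Same dimensions, spacing and origin (mm tolerance `1e-6`).
#'
#' @param a,b `image_volume` or `label_volume` objects.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) < 1e-6 &&
    max(abs(a$origin - b$origin)) < 1e-6
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " must share the same grid (dim/spacing/origin)")
  invisible(TRUE)
}

#' Physical coordinates of voxel centres
#'
#' @param volume a `ct_volume`.
#' @param indices optional integer matrix (rows = voxels, 1-based i,j,k);
#'   default all voxels in array order.
#' @return Numeric matrix with columns x, y, z in mm.
#' @export
voxel_centers <- function(volume, indices = NULL) {
  if (is.null(indices)) {
    d <- dim(volume$voxels)
    indices <- arrayInd(seq_len(prod(d)), d)
  }
  sweep(sweep(indices - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' Linear indices -> physical mm coordinates
#' @noRd
linear_to_mm <- function(volume, lin) {
  voxel_centers(volume, arrayInd(lin, dim(volume$voxels)))
}
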