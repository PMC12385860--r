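#' Resample a volume to a target spacing
#'
#' The output grid keeps the input origin and covers the input physical
#' extent: the output dimension along each axis is
#' `ceiling(dim * spacing / target_spacing)`, so anatomy is never
#' truncated (the extent may grow by up to one output voxel per axis).
#' Image volumes are interpolated trilinearly; label volumes by nearest
#' neighbour, which never invents classes.
#'
#' @param volume an `image_volume` or `label_volume`.
#' @param target_spacing numeric length-3, strictly positive (mm).
#' @param fill value for output voxels beyond the input field (HU volumes
#'   only; default -1024, air). Labels use 0 (background).
#' @return A volume of the same kind on the new grid.
#' @export
resample <- function(volume, target_spacing, fill = -1024) {
  stopifnot(inherits(volume, "ct_volume"))
  target_spacing <- check_spacing(target_spacing)
  d <- dim(volume$voxels)
  if (max(abs(volume$spacing - target_spacing)) < 1e-9) return(volume)
  odim <- as.integer(ceiling(d * volume$spacing / target_spacing))
  resample_onto(volume,
                list(dim = odim, spacing = target_spacing,
                     origin = volume$origin),
                fill = fill)
}

# Resample (optionally through an affine pull-back map q = A p + t) onto an
# explicit grid; used by resample(), apply_transform() and predict().
resample_onto <- function(volume, grid, A = diag(3), tr = c(0, 0, 0),
                          fill = -1024, with_mask = FALSE) {
  is_lab <- inherits(volume, "label_volume")
  res <- cpp_resample(as.numeric(volume$voxels), dim(volume$voxels),
                      volume$spacing, volume$origin,
                      as.integer(grid$dim), grid$spacing, grid$origin,
                      A, tr, linear = !is_lab,
                      fill = if (is_lab) 0 else fill)
  arr <- array(res$values, dim = grid$dim)
  out <- if (is_lab) {
    label_volume(array(as.integer(round(arr)), dim = grid$dim),
                 grid$spacing, grid$origin)
  } else {
    image_volume(arr, grid$spacing, grid$origin)
  }
  if (with_mask) {
    list(volume = out, inside = array(res$inside, dim = grid$dim))
  } else {
    out
  }
}

grid_of <- function(volume) {
  list(dim = dim(volume$voxels), spacing = volume$spacing,
       origin = volume$origin)
}
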