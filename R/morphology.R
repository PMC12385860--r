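#' Euclidean distance to a foreground set, in millimetres
#'
#' Exact distance from every voxel centre to the nearest foreground voxel
#' centre, honouring anisotropic spacing (separable lower-envelope
#' transform). Foreground voxels get distance 0.
#'
#' @param mask logical/0-1 3-D array.
#' @param spacing voxel spacing (mm).
#' @return Numeric 3-D array of distances (mm).
#' @export
distance_to_mask <- function(mask, spacing) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  if (!any(mask)) return(array(Inf, dim = d))
  sq <- cpp_edt_sq(as.logical(mask), as.integer(d), check_spacing(spacing))
  array(sqrt(sq), dim = d)
}

#' Dilate a binary mask by a physical radius
#'
#' Morphological dilation with a spherical structuring element specified in
#' millimetres: a voxel is foreground in the result iff its centre lies
#' within `radius_mm` (Euclidean, physical units) of some input foreground
#' voxel centre. On anisotropic grids the element is therefore ellipsoidal
#' in index space. Implemented through the exact distance transform, so it
#' agrees with brute-force distance thresholding.
#'
#' @param mask logical/0-1 3-D array.
#' @param radius_mm dilation radius (mm), `>= 0`.
#' @param spacing voxel spacing (mm).
#' @return Logical 3-D array.
#' @export
dilate_mm <- function(mask, radius_mm, spacing) {
  stopifnot(radius_mm >= 0)
  if (radius_mm == 0) return(array(as.logical(mask), dim = dim(mask)))
  d <- distance_to_mask(mask, spacing)
  # half-ulp slack so exact-radius voxels are included regardless of
  # floating-point rounding in the transform
  array(d <= radius_mm + 1e-9, dim = dim(mask))
}

#' Label connected components of a binary mask
#'
#' Deterministic labelling (components numbered in raster-scan order of
#' their first voxel) under 6-, 18- or 26-connectivity.
#'
#' @param mask logical/0-1 3-D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer 3-D array of component labels (0 = background) with
#'   attribute `n_components`.
#' @export
connected_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  d <- dim(mask)
  lab <- cpp_label_components(as.logical(mask), as.integer(d),
                              as.integer(connectivity))
  n <- attr(lab, "n_components")
  lab <- array(lab, dim = d)
  attr(lab, "n_components") <- n
  lab
}

# Closest voxel-centre pair between two components given as linear indices
# into a volume's grid. Returns endpoints (mm), their linear indices and
# the distance.
nearest_pair_mm <- function(volume, lin_a, lin_b) {
  a <- linear_to_mm(volume, lin_a)
  b <- linear_to_mm(volume, lin_b)
  np <- cpp_nearest_pair(a, b)
  list(p_a = a[np$i, ], p_b = b[np$j, ],
       lin_a = lin_a[np$i], lin_b = lin_b[np$j],
       distance = np$distance)
}

# Linear indices of voxels crossed by the straight segment p0 -> p1 (mm).
segment_voxels <- function(volume, p0, p1) {
  cpp_segment_voxels(as.numeric(p0), as.numeric(p1),
                     dim(volume$voxels), volume$spacing, volume$origin)
}

# Surface voxels of a labelled component set: foreground voxels with at
# least one 6-neighbour outside the mask (or on the volume border). Used to
# shrink the candidate set for nearest-pair searches.
surface_voxels <- function(mask) {
  d <- dim(mask)
  m <- array(as.logical(mask), dim = d)
  interior <- array(TRUE, dim = d)
  shift_and <- function(acc, src) acc & src
  pad_slice <- function(along, from) {
    out <- array(FALSE, dim = d)
    idx_src <- idx_dst <- lapply(d, seq_len)
    n <- d[along]
    if (from > 0) {
      idx_dst[[along]] <- seq_len(n - from)
      idx_src[[along]] <- seq_len(n - from) + from
    } else {
      idx_dst[[along]] <- seq_len(n + from) - from
      idx_src[[along]] <- seq_len(n + from)
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) {
    interior <- shift_and(interior, pad_slice(ax, 1L))
    interior <- shift_and(interior, pad_slice(ax, -1L))
  }
  m & !interior
}
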