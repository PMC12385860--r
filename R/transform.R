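#' Affine transforms between physical frames
#'
#' An `affine_transform` maps physical points (mm) of one volume's frame
#' into another's: `y = M x + t`. A rigid transform is the special case of
#' an orthonormal `M` with determinant +1, built from Euler angles.
#'
#' @param matrix invertible 3x3 matrix.
#' @param translation numeric length-3 (mm).
#' @param rigid logical flag; if `TRUE` the matrix must be a rotation
#'   (orthonormal, det +1, checked to 1e-6).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0),
                             rigid = FALSE) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  dt <- det(matrix)
  if (abs(dt) < 1e-8)
    stop("transform matrix is singular (|det| = ", format(abs(dt)), ")")
  if (rigid) {
    err <- max(abs(crossprod(matrix) - diag(3)))
    if (err > 1e-6 || dt < 0)
      stop("rigid transform requires an orthonormal matrix with det +1")
  }
  structure(list(matrix = matrix, translation = translation, rigid = rigid),
            class = "affine_transform")
}

#' Rigid transform from Euler angles
#'
#' Rotation about the given centre (mm) by angles (degrees) applied in
#' z, y, x order, followed by a translation.
#'
#' @param angles_deg numeric length-3, rotations about x, y, z axes (deg).
#' @param translation numeric length-3 (mm).
#' @param center rotation centre (mm); default the origin.
#' @return An `affine_transform` with the rigid flag set.
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0),
                            translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  a <- angles_deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  M <- Rz %*% Ry %*% Rx
  # y = M (x - c) + c + t  =  M x + (c + t - M c)
  affine_transform(M, as.numeric(center + translation - M %*% center),
                   rigid = TRUE)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>", if (x$rigid) "(rigid)" else "", "\n")
  cat("matrix:\n")
  print(round(x$matrix, 6))
  cat("translation (mm):", paste(round(x$translation, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Invert an affine transform
#' @param transform an `affine_transform`.
#' @return The inverse `affine_transform`.
#' @export
invert_transform <- function(transform) {
  Mi <- solve(transform$matrix)
  affine_transform(Mi, -as.numeric(Mi %*% transform$translation),
                   rigid = transform$rigid)
}

#' Compose two affine transforms
#'
#' Returns the transform applying `b` first, then `a`:
#' `x -> a(b(x))`.
#'
#' @param a,b `affine_transform` objects.
#' @return The composed `affine_transform`.
#' @export
compose_transforms <- function(a, b) {
  affine_transform(a$matrix %*% b$matrix,
                   as.numeric(a$matrix %*% b$translation) + a$translation,
                   rigid = a$rigid && b$rigid)
}

#' Apply a transform to point coordinates
#' @param transform an `affine_transform`.
#' @param points numeric matrix (rows = points, columns x,y,z in mm) or a
#'   single length-3 vector.
#' @return Transformed coordinates, same shape as the input.
#' @export
transform_points <- function(transform, points) {
  single <- is.null(dim(points))
  pts <- if (single) matrix(points, 1) else as.matrix(points)
  out <- sweep(pts %*% t(transform$matrix), 2, transform$translation, "+")
  if (single) as.numeric(out) else out
}

#' Resample a volume through a transform onto a reference grid
#'
#' `transform` maps points of the volume's (moving) frame into the
#' reference (fixed) frame; each output voxel centre `p` is filled by
#' interpolating the input at `transform^{-1}(p)`. Linear interpolation for
#' HU volumes, nearest neighbour for label volumes and binary masks, so
#' masks stay binary.
#'
#' @param volume an `image_volume` or `label_volume` (masks: a
#'   `label_volume` or a logical/integer array matching the moving grid).
#' @param transform an `affine_transform` (moving frame -> fixed frame).
#' @param reference a `ct_volume` (or grid list) defining the output grid.
#' @param fill value for out-of-field voxels (HU volumes; labels get 0).
#' @return A volume of the input kind on the reference grid.
#' @export
apply_transform <- function(volume, transform, reference, fill = -1024) {
  grid <- if (inherits(reference, "ct_volume")) grid_of(reference) else reference
  inv <- invert_transform(transform)
  resample_onto(volume, grid, A = inv$matrix, tr = inv$translation,
                fill = fill)
}

# Summaries used by tests and the registration report: how far a transform
# is from the identity, as a translation magnitude at the volume centre and
# a rotation angle.
transform_deviation <- function(transform, center = c(0, 0, 0)) {
  disp <- transform_points(transform, center) - center
  M <- transform$matrix
  # rotation angle from the closest rotation (polar factor)
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  list(translation_mm = sqrt(sum(disp^2)), rotation_deg = ang)
}
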