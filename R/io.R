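#' Read a NIfTI volume
#'
#' Reads a 3-D NIfTI-1 file (`.nii` or `.nii.gz`) into an [image_volume()]
#' or, with `labels = TRUE`, a [label_volume()]. Spacing is taken from the
#' header `pixdim`; the origin from the stored transform's translation.
#' Volumes are assumed axis-aligned (the package's phantom and mask outputs
#' always are); any rotational part of the stored transform is ignored.
#'
#' @param path path to a readable NIfTI file.
#' @param labels logical; coerce to a label volume (integer classes 0..3)?
#' @return An `image_volume` or `label_volume`.
#' @export
read_volume <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.vector(img), dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected a 3-D image, got rank ", length(d))
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  arr <- array(as.numeric(img), dim = d)
  if (labels) {
    label_volume(array(as.integer(round(arr)), dim = d), spacing, origin)
  } else {
    image_volume(arr, spacing, origin)
  }
}

#' Write a volume as NIfTI
#'
#' Label volumes are stored as unsigned 8-bit integers (exact round-trip);
#' image volumes as 32-bit floats. The grid geometry is written as an
#' axis-aligned transform `diag(spacing)` with the origin as translation.
#'
#' @param volume an `image_volume` or `label_volume`.
#' @param path output path (`.nii` or `.nii.gz`); parent must be writable.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  is_lab <- inherits(volume, "label_volume")
  arr <- volume$voxels
  storage.mode(arr) <- if (is_lab) "integer" else "double"
  xfm <- diag(4)
  diag(xfm)[1:3] <- volume$spacing
  xfm[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::sform(img) <- structure(xfm, code = 2L)
  RNifti::qform(img) <- structure(xfm, code = 2L)
  datatype <- if (is_lab) "uint8" else "float"
  ok <- try(RNifti::writeNifti(img, path, datatype = datatype), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write NIfTI file: ", path)
  if (!file.exists(path)) stop("could not write NIfTI file: ", path)
  invisible(path)
}
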