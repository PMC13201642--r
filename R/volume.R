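#' Construct a volume
#'
#' A volume is a 3-D scalar intensity field together with its physical voxel
#' spacing in millimetres. It is the common currency of every stage of the
#' toolkit: the phantom generator produces one, the preprocessing pipeline
#' transforms one, and the evaluation metrics consume them (directly or as
#' binary masks sharing the same geometry).
#'
#' @param data 3-D numeric array of voxel intensities; all values finite.
#' @param spacing numeric vector of length 3, millimetres per voxel along
#'   each axis; strictly positive.
#' @return An object of class `wmh_volume`: a list with elements `data`
#'   and `spacing`.
#' @examples
#' v <- as_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(0.5, 0.5, 3))
#' dim(v$data)
#' @export
as_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3-D array", call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume data must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "wmh_volume")
}

#' @export
print.wmh_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<wmh_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Test for a volume object
#' @param x object to test.
#' @return `TRUE` if `x` is a `wmh_volume`.
#' @export
is_volume <- function(x) inherits(x, "wmh_volume")

# Accept either a wmh_volume or a bare 3-D array; return the array.
vol_data <- function(x) {
  if (is_volume(x)) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a wmh_volume or 3-D array", call. = FALSE)
}

vol_spacing <- function(x, default = c(1, 1, 1)) {
  if (is_volume(x)) x$spacing else default
}

# Coerce a mask argument to a logical 3-D array aligned with `ref` (if given).
as_mask <- function(mask, ref = NULL) {
  m <- if (is_volume(mask)) mask$data else mask
  if (!is.array(m) || length(dim(m)) != 3L)
    stop("mask must be a 3-D array", call. = FALSE)
  m <- m != 0
  if (!is.null(ref) && !identical(dim(m), dim(vol_data(ref))))
    stop("mask and volume dimensions differ", call. = FALSE)
  m
}

#' Read a 3-D volume from a NIfTI file
#'
#' Reads a NIfTI-1 image (`.nii` / `.nii.gz`), extracting voxel spacing from
#' the header. Only 3-D payloads are accepted.
#'
#' @param path path to a NIfTI file.
#' @return A [as_volume()] object.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D NIfTI payload, got ", length(d), " dimensions",
         call. = FALSE)
  as_volume(array(as.numeric(img), d), spacing = RNifti::pixdim(img)[1:3])
}

#' Write a volume to a NIfTI file
#'
#' @param volume a [as_volume()] object (or 3-D array, written at unit
#'   spacing).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype NIfTI storage type; `"double"` (default) preserves values
#'   exactly, `"uint8"` suits binary masks.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "double") {
  dat <- vol_data(volume)
  sp <- vol_spacing(volume)
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
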