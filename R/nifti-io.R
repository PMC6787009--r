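# NIfTI-1 input/output built on RNifti.  The stored sform is the package's
# voxel-to-world affine (0-based indices, RAS+), so geometry survives a
# write/read round trip; displacement fields travel as 5D images with the
# vector component in the 5th dimension, the NIfTI vector convention.

niftiFromArray <- function(arr, voxelSize, affine) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- voxelSize
  # the sform is authoritative; setting it after pixdim keeps both in step
  im <- RNifti::`sform<-`(im, structure(affine, code = 2L))
  im
}

plainArray <- function(x) {
  d <- dim(x)
  x <- as.vector(x)
  dim(x) <- d
  x
}

affineFromNifti <- function(im) {
  A <- unclass(RNifti::xform(im))
  attributes(A) <- list(dim = c(4L, 4L))
  A
}

#' Read and write volumes as NIfTI-1
#'
#' `readVolume()`/`writeVolume()` handle 3D scalar volumes,
#' `readTimeSeries()`/`writeTimeSeries()` 4D series, and
#' `readDisplacementField()`/`writeDisplacementField()` dense warps stored
#' as 5D NIfTI with the displacement component in dimension 5.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param x the object to write.
#' @return readers return the corresponding class; writers return the path
#'   invisibly.
#' @name nifti-io
NULL

#' @rdname nifti-io
#' @export
readVolume <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- plainArray(as.array(im))
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume", call. = FALSE)
  scalarVolume(arr, voxelSize = RNifti::pixdim(im)[1:3],
               affine = affineFromNifti(im))
}

#' @rdname nifti-io
#' @export
writeVolume <- function(x, path) {
  RNifti::writeNifti(niftiFromArray(x@data, x@voxelSize, x@affine), path)
  invisible(path)
}

#' @rdname nifti-io
#' @export
readTimeSeries <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- plainArray(as.array(im))
  if (length(dim(arr)) != 4L) stop("expected a 4D NIfTI series", call. = FALSE)
  timeSeriesVolume(arr, voxelSize = RNifti::pixdim(im)[1:3],
                   affine = affineFromNifti(im))
}

#' @rdname nifti-io
#' @export
writeTimeSeries <- function(x, path) {
  RNifti::writeNifti(niftiFromArray(x@data, x@voxelSize, x@affine), path)
  invisible(path)
}

#' @rdname nifti-io
#' @export
readDisplacementField <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- plainArray(as.array(im))
  d <- dim(arr)
  if (length(d) == 5L && d[4L] == 1L && d[5L] == 3L)
    arr <- array(arr, c(d[1:3], 3L))
  else if (!(length(d) == 4L && d[4L] == 3L))
    stop("expected a 5D vector NIfTI (x, y, z, 1, 3)", call. = FALSE)
  displacementField(arr, voxelSize = RNifti::pixdim(im)[1:3],
                    affine = affineFromNifti(im))
}

#' @rdname nifti-io
#' @export
writeDisplacementField <- function(x, path) {
  d <- gridDim(x)
  arr <- array(x@vectors, c(d, 1L, 3L))
  RNifti::writeNifti(niftiFromArray(arr, x@voxelSize, x@affine), path)
  invisible(path)
}
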