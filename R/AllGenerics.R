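#' Grid geometry accessors
#'
#' `voxelSize()` returns mm per axis, `affine()` the 4x4 voxel-to-world map
#' (0-based voxel indices, RAS+ mm), `gridDim()` the lattice dimensions and
#' `volData()` the underlying array.
#'
#' @param x a volumetric object.
#' @return `voxelSize`: numeric(3); `affine`: 4x4 matrix; `gridDim`:
#'   integer(3); `volData`: the array slot.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname grid-accessors
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))
#' @rdname grid-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname grid-accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname grid-accessors
#' @export
setMethod("voxelSize", "VolumeGrid", function(x) x@voxelSize)
#' @rdname grid-accessors
#' @export
setMethod("affine", "VolumeGrid", function(x) x@affine)

#' Gaussian smoothing
#'
#' @param x object to smooth.
#' @param sigmaMm isotropic Gaussian sigma in mm (converted to voxels per
#'   axis); 0 is the identity.
#' @param ... method arguments.
#' @return an object of the same class as `x`.
#' @seealso [gaussianSmooth,ScalarVolume-method]
#' @export
setGeneric("gaussianSmooth", function(x, sigmaMm, ...)
  standardGeneric("gaussianSmooth"))

#' ROI and connectome accessors
#'
#' @param x an object with named regions.
#' @return `roiNames`: character vector; `counts`: the raw count matrix;
#'   `adjacency`: the binarised logical adjacency matrix.
#' @name roi-accessors
NULL

#' @rdname roi-accessors
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))
#' @rdname roi-accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname roi-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
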