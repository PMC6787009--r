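#' Construct a ScalarVolume
#'
#' @param data 3D numeric array (or a vector with `dim` supplied).
#' @param voxelSize numeric(3), mm per axis; default 1 mm isotropic.
#' @param affine 4x4 voxel-to-world matrix (0-based indices, RAS+ mm);
#'   defaults to `diag(voxelSize)` with zero translation.
#' @param dim lattice dimensions when `data` is not already an array.
#' @return a [ScalarVolume-class].
#' @examples
#' v <- scalarVolume(array(0, c(4, 4, 4)), voxelSize = c(2, 2, 2))
#' gridDim(v)
#' @export
scalarVolume <- function(data, voxelSize = c(1, 1, 1), affine = NULL,
                         dim = NULL) {
  if (!is.null(dim)) data <- array(data, dim)
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxelSize
  }
  new("ScalarVolume", data = data, voxelSize = as.numeric(voxelSize),
      affine = affine)
}

#' Construct a TimeSeriesVolume
#'
#' @param data 4D numeric array, time last.
#' @inheritParams scalarVolume
#' @return a [TimeSeriesVolume-class].
#' @export
timeSeriesVolume <- function(data, voxelSize = c(1, 1, 1), affine = NULL) {
  if (is.null(affine)) { affine <- diag(4); diag(affine)[1:3] <- voxelSize }
  new("TimeSeriesVolume", data = data, voxelSize = as.numeric(voxelSize),
      affine = affine)
}

#' Construct a DisplacementField
#'
#' Vectors are in voxel units of the reference grid, pull convention: the
#' sample for reference voxel x is taken at moving-space position x + u(x).
#'
#' @param vectors 4D array (x, y, z, 3), or `0` for a zero field when
#'   `reference` is given.
#' @param reference a [VolumeGrid-class] object supplying the geometry.
#' @inheritParams scalarVolume
#' @return a [DisplacementField-class].
#' @export
displacementField <- function(vectors, reference = NULL,
                              voxelSize = c(1, 1, 1), affine = NULL) {
  if (!is.null(reference)) {
    voxelSize <- voxelSize(reference); affine <- affine(reference)
    if (identical(vectors, 0))
      vectors <- array(0, c(gridDim(reference), 3L))
  }
  if (is.null(affine)) { affine <- diag(4); diag(affine)[1:3] <- voxelSize }
  new("DisplacementField", vectors = vectors,
      voxelSize = as.numeric(voxelSize), affine = affine)
}

#' Construct a DirectionField
#'
#' @param vectors 4D array (x, y, z, 3) of unit vectors (sign-ambiguous).
#' @param mask 3D tracking mask (logical or 0/1).
#' @inheritParams scalarVolume
#' @return a [DirectionField-class].
#' @export
directionField <- function(vectors, mask, voxelSize = c(1, 1, 1),
                           affine = NULL) {
  if (is.null(affine)) { affine <- diag(4); diag(affine)[1:3] <- voxelSize }
  new("DirectionField", vectors = vectors, mask = (mask > 0) + 0,
      voxelSize = as.numeric(voxelSize), affine = affine)
}

#' @rdname grid-accessors
#' @export
setMethod("gridDim", "ScalarVolume", function(x) dim(x@data))
#' @rdname grid-accessors
#' @export
setMethod("gridDim", "TimeSeriesVolume", function(x) dim(x@data)[1:3])
#' @rdname grid-accessors
#' @export
setMethod("gridDim", "DisplacementField", function(x) dim(x@vectors)[1:3])
#' @rdname grid-accessors
#' @export
setMethod("gridDim", "DirectionField", function(x) dim(x@vectors)[1:3])
#' @rdname grid-accessors
#' @export
setMethod("gridDim", "ROISet", function(x) dim(x@masks[[1]]))
#' @rdname grid-accessors
#' @export
setMethod("volData", "ScalarVolume", function(x) x@data)
#' @rdname grid-accessors
#' @export
setMethod("volData", "TimeSeriesVolume", function(x) x@data)
#' @rdname grid-accessors
#' @export
setMethod("volData", "DisplacementField", function(x) x@vectors)
#' @rdname grid-accessors
#' @export
setMethod("volData", "DirectionField", function(x) x@vectors)

#' Number of time points of a TimeSeriesVolume
#' @param x a [TimeSeriesVolume-class].
#' @return integer number of time points.
#' @export
nTimepoints <- function(x) dim(x@data)[4L]

setMethod("show", "ScalarVolume", function(object) {
  cat("ScalarVolume", paste(gridDim(object), collapse = " x "),
      "voxels,", paste(signif(object@voxelSize, 4), collapse = " x "),
      "mm\n  range:", paste(signif(range(object@data), 4), collapse = " .. "),
      "\n")
})
setMethod("show", "TimeSeriesVolume", function(object) {
  cat("TimeSeriesVolume", paste(gridDim(object), collapse = " x "),
      "voxels x", nTimepoints(object), "time points,",
      paste(signif(object@voxelSize, 4), collapse = " x "), "mm\n")
})
setMethod("show", "DisplacementField", function(object) {
  n <- sqrt(rowSums(matrix(object@vectors, ncol = 3)^2))
  cat("DisplacementField on", paste(gridDim(object), collapse = " x "),
      "grid; max |u| =", signif(max(n), 4), "voxels\n")
})
setMethod("show", "DirectionField", function(object) {
  cat("DirectionField on", paste(gridDim(object), collapse = " x "),
      "grid;", sum(object@mask > 0), "voxels in tracking mask\n")
})

#' Voxel-to-world and world-to-voxel coordinate maps
#'
#' `worldFromVoxel()` applies the affine to (possibly fractional) 0-based
#' voxel indices; `voxelFromWorld()` applies its inverse.  The two
#' round-trip to numerical precision.
#'
#' @param x a volumetric object (any [VolumeGrid-class]) or a 4x4 affine.
#' @param index,world numeric 3-vector or N x 3 matrix of coordinates.
#' @return coordinates in the target space, same shape as the input.
#' @examples
#' v <- scalarVolume(array(0, c(8, 8, 8)), voxelSize = c(2, 2, 2))
#' worldFromVoxel(v, c(1, 2, 3))
#' @export
worldFromVoxel <- function(x, index) {
  A <- if (is.matrix(x) && all(dim(x) == 4)) x else affine(x)
  applyAffine(A, index)
}

#' @rdname worldFromVoxel
#' @export
voxelFromWorld <- function(x, world) {
  A <- if (is.matrix(x) && all(dim(x) == 4)) x else affine(x)
  if (abs(det(A)) < .Machine$double.eps * 64)
    stop("affine is not invertible", call. = FALSE)
  applyAffine(solve(A), world)
}

applyAffine <- function(A, pts) {
  vec <- !is.matrix(pts)
  if (vec) pts <- matrix(pts, nrow = 1)
  out <- pts %*% t(A[1:3, 1:3]) +
    matrix(A[1:3, 4], nrow(pts), 3, byrow = TRUE)
  if (vec) drop(out) else out
}

#' Warp a volume through a displacement field
#'
#' Pull-resamples `moving` onto the grid of `field`: the output value at
#' reference voxel x is the interpolated value of `moving` at x + u(x).
#' Samples falling outside the moving grid take the value 0.
#'
#' @param moving a [ScalarVolume-class].
#' @param field a [DisplacementField-class] defining the output grid.
#' @param interpolation `"trilinear"` (default) or `"nearest"` (for masks).
#' @return a [ScalarVolume-class] on the reference grid.
#' @examples
#' v <- scalarVolume(array(rnorm(512), c(8, 8, 8)))
#' zero <- displacementField(0, reference = v)
#' identical(volData(resampleVolume(v, zero)), volData(v))
#' @export
resampleVolume <- function(moving, field,
                           interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopIfDifferentGrid(moving, field, "volume and field")
  d <- gridDim(field)
  pts <- gridCoords(d) + matrix(field@vectors, ncol = 3L)
  smp <- if (interpolation == "trilinear") trilinearSample else nearestSample
  scalarVolume(array(smp(moving@data, pts), d),
               voxelSize = field@voxelSize, affine = field@affine)
}

#' Compose two displacement fields
#'
#' Returns the field equivalent to applying `g` first and then `f` under
#' the pull convention: (f o g)(x) = g(x) + f(x + g(x)), with f
#' interpolated componentwise.
#'
#' @param f,g [DisplacementField-class] objects on the same reference grid.
#' @return the composed [DisplacementField-class].
#' @export
composeFields <- function(f, g) {
  stopIfDifferentGrid(f, g, "fields")
  d <- gridDim(f)
  pts <- gridCoords(d) + matrix(g@vectors, ncol = 3L)
  comp <- array(0, c(d, 3L))
  for (k in 1:3)
    comp[, , , k] <- array(trilinearSample(f@vectors[, , , k], pts,
                                           mode = "clamp"), d)
  displacementField(comp + g@vectors, reference = f)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves v(x) = -u(x + v(x)) so that composing the field with its inverse
#' is close to the identity.  Iteration stops when the largest update falls
#' below `tol` (voxels) or after `maxIter` sweeps.  The achieved round-trip
#' residual max |(u o u^-1)(x)| is attached as attribute `"residual"`; a
#' residual above `10 * tol` raises a warning (never silent failure).
#'
#' @param f a [DisplacementField-class]; must be smooth enough to be
#'   invertible (positive Jacobian of x + u).
#' @param maxIter maximum fixed-point sweeps (default 30).
#' @param tol convergence tolerance in voxels (default 0.01).
#' @return the inverse [DisplacementField-class] with attribute
#'   `"residual"`.
#' @export
invertField <- function(f, maxIter = 30L, tol = 0.01) {
  d <- gridDim(f)
  x <- gridCoords(d)
  u <- matrix(f@vectors, ncol = 3L)
  v <- -u  # first-order guess
  comps <- lapply(1:3, function(k) f@vectors[, , , k])
  for (it in seq_len(maxIter)) {
    pts <- x + v
    vNew <- -vapply(comps, function(cmp) trilinearSample(cmp, pts,
                                                         mode = "clamp"),
                    numeric(nrow(x)))
    delta <- max(abs(vNew - v))
    v <- vNew
    if (delta < tol) break
  }
  inv <- displacementField(array(v, c(d, 3L)), reference = f)
  res <- composeFields(f, inv)@vectors
  residual <- max(sqrt(rowSums(matrix(res, ncol = 3L)^2)))
  if (residual > 10 * tol)
    warning("field inversion did not converge: round-trip residual ",
            signif(residual, 3), " voxels", call. = FALSE)
  attr(inv, "residual") <- residual
  inv
}

#' Gaussian smoothing of a scalar volume
#'
#' Separable Gaussian with `sigmaMm` converted to voxels per axis, reflect
#' boundary handling (the global mean is preserved exactly); `sigmaMm = 0`
#' is the identity.
#'
#' @param x a [ScalarVolume-class].
#' @param sigmaMm non-negative isotropic sigma in mm.
#' @return the smoothed [ScalarVolume-class].
#' @export
setMethod("gaussianSmooth", "ScalarVolume", function(x, sigmaMm) {
  if (length(sigmaMm) != 1L || !is.finite(sigmaMm) || sigmaMm < 0)
    stop("sigmaMm must be a single non-negative value", call. = FALSE)
  if (sigmaMm == 0) return(x)
  scalarVolume(sepGaussSmooth(x@data, sigmaMm / x@voxelSize),
               voxelSize = x@voxelSize, affine = x@affine)
})
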