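#' @import methods
NULL

#' Virtual base class for objects living on a 3D voxel lattice
#'
#' Holds the geometry shared by all volumetric classes: voxel size in mm and
#' the 4x4 voxel-index-to-world affine (RAS+ convention, 0-based indices).
#'
#' @slot voxelSize numeric length-3, mm per axis, strictly positive.
#' @slot affine 4x4 numeric matrix mapping 0-based voxel indices to world mm.
#' @keywords internal
#' @exportClass VolumeGrid
setClass("VolumeGrid",
  representation("VIRTUAL", voxelSize = "numeric", affine = "matrix"))

validGrid <- function(object) {
  msg <- character()
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 strictly positive finite values")
  if (!all(dim(object@affine) == c(4L, 4L)) || any(!is.finite(object@affine)))
    msg <- c(msg, "affine must be a finite 4x4 matrix")
  else if (abs(det(object@affine)) < .Machine$double.eps * 64)
    msg <- c(msg, "affine must be invertible")
  msg
}

#' Scalar volume on a 3D lattice
#'
#' The workhorse container for connectivity maps, t-maps, p-maps and binary
#' masks: one real value per voxel plus grid geometry.
#'
#' @slot data 3D numeric array.
#' @slot voxelSize,affine grid geometry, see [VolumeGrid-class].
#' @seealso [scalarVolume()], [readVolume()], [resampleVolume()]
#' @exportClass ScalarVolume
setClass("ScalarVolume", contains = "VolumeGrid",
  representation(data = "array"),
  validity = function(object) {
    msg <- validGrid(object)
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(msg)) msg else TRUE
  })

#' 4D BOLD-like time-series volume
#'
#' One time series of length T per voxel, stored as an x-y-z-t array.
#'
#' @slot data 4D numeric array, last dimension is time (T >= 2).
#' @slot voxelSize,affine grid geometry.
#' @seealso [timeSeriesVolume()], [seedCorrelationMap()]
#' @exportClass TimeSeriesVolume
setClass("TimeSeriesVolume", contains = "VolumeGrid",
  representation(data = "array"),
  validity = function(object) {
    msg <- validGrid(object)
    if (length(dim(object@data)) != 4L)
      msg <- c(msg, "data must be a 4D array (x, y, z, t)")
    else if (dim(object@data)[4L] < 2L)
      msg <- c(msg, "need at least 2 time points")
    if (length(msg)) msg else TRUE
  })

#' Dense displacement field (nonlinear warp)
#'
#' One 3-vector per voxel of the reference grid, in voxel units, pull
#' convention: the resampled value at reference voxel x is taken from the
#' moving image at position x + u(x).
#'
#' @slot vectors 4D numeric array (x, y, z, 3), finite everywhere.
#' @slot voxelSize,affine geometry of the reference (fixed) grid.
#' @seealso [displacementField()], [composeFields()], [invertField()]
#' @exportClass DisplacementField
setClass("DisplacementField", contains = "VolumeGrid",
  representation(vectors = "array"),
  validity = function(object) {
    msg <- validGrid(object)
    d <- dim(object@vectors)
    if (length(d) != 4L || d[4L] != 3L)
      msg <- c(msg, "vectors must be a 4D array with last dimension 3")
    else if (any(!is.finite(object@vectors)))
      msg <- c(msg, "vectors must be finite everywhere")
    if (length(msg)) msg else TRUE
  })

#' Fibre direction field for deterministic tracking
#'
#' A unit 3-vector per voxel (axis convention: the sign is arbitrary) plus a
#' binary tracking mask; stands in for the peak-orientation field that a
#' spherical-deconvolution reconstruction would supply.
#'
#' @slot vectors 4D numeric array (x, y, z, 3); unit norm inside the mask.
#' @slot mask 3D array, nonzero where tracking is allowed.
#' @slot voxelSize,affine grid geometry.
#' @seealso [directionField()], [trackStreamlines()]
#' @exportClass DirectionField
setClass("DirectionField", contains = "VolumeGrid",
  representation(vectors = "array", mask = "array"),
  validity = function(object) {
    msg <- validGrid(object)
    d <- dim(object@vectors)
    if (length(d) != 4L || d[4L] != 3L)
      msg <- c(msg, "vectors must be a 4D array with last dimension 3")
    if (length(dim(object@mask)) != 3L ||
        !isTRUE(all(dim(object@mask) == d[1:3])))
      msg <- c(msg, "mask must be a 3D array matching the vector grid")
    else {
      inm <- which(object@mask > 0)
      if (length(inm)) {
        v <- matrix(object@vectors, ncol = 3L)[inm, , drop = FALSE]
        n <- sqrt(rowSums(v^2))
        if (any(abs(n - 1) > 1e-6))
          msg <- c(msg, "vectors must be unit norm inside the mask")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Named set of binary masks on one grid (seeds or regions of interest)
#'
#' Used both for the 40 seed masks that drive the individual DMN maps and
#' for the regions of interest extracted from the thresholded group map.
#' Overlapping masks are only tolerated for user-supplied sets.
#'
#' @slot masks named list of logical 3D arrays, all on the same grid.
#' @slot provenance either `"thresholded-component"` or `"user-supplied"`.
#' @slot voxelSize,affine grid geometry.
#' @seealso [roiSet()], [extractRois()], [roiMeanTimeseries()]
#' @exportClass ROISet
setClass("ROISet", contains = "VolumeGrid",
  representation(masks = "list", provenance = "character"),
  validity = function(object) {
    msg <- validGrid(object)
    nm <- names(object@masks)
    if (length(object@masks) < 1L) msg <- c(msg, "need at least one mask")
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
      msg <- c(msg, "masks must have unique non-empty names")
    if (!object@provenance %in% c("thresholded-component", "user-supplied"))
      msg <- c(msg, "provenance must be 'thresholded-component' or 'user-supplied'")
    for (m in object@masks) {
      if (length(dim(m)) != 3L) { msg <- c(msg, "each mask must be 3D"); break }
      if (!any(m)) { msg <- c(msg, "masks must be non-empty"); break }
    }
    if (length(msg)) msg else TRUE
  })

#' ROI-by-ROI correlation matrix
#'
#' Symmetric matrix of full or partial Pearson correlations with unit
#' diagonal (the partial-correlation diagonal is fixed to 1 by convention).
#'
#' @slot values n x n numeric matrix.
#' @slot roiNames character vector of region names.
#' @slot kind `"full"` or `"partial"`.
#' @seealso [correlationMatrix()], [partialCorrelationMatrix()]
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
  representation(values = "matrix", roiNames = "character", kind = "character"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    if (length(object@roiNames) != nrow(v))
      msg <- c(msg, "roiNames length must match matrix dimension")
    if (!object@kind %in% c("full", "partial"))
      msg <- c(msg, "kind must be 'full' or 'partial'")
    if (max(abs(v - t(v))) > 1e-10) msg <- c(msg, "matrix must be symmetric")
    if (max(abs(diag(v) - 1)) > 1e-10) msg <- c(msg, "diagonal must be 1")
    off <- v[row(v) != col(v)]
    if (length(off) && (max(off) > 1 + 1e-10 || min(off) < -1 - 1e-10))
      msg <- c(msg, "off-diagonals must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  })

#' Streamline-count connectome
#'
#' Symmetric matrix of non-negative streamline endpoint counts with zero
#' diagonal, plus the count threshold at which [adjacency()] binarises it.
#'
#' @slot counts n x n non-negative matrix, symmetric, zero diagonal.
#' @slot roiNames region names.
#' @slot binariseThreshold count threshold (edges are counts >= threshold).
#' @seealso [endpointsConnectome()], [binarizeConnectome()], [graphMetrics()]
#' @exportClass Connectome
setClass("Connectome",
  representation(counts = "matrix", roiNames = "character",
                 binariseThreshold = "numeric"),
  validity = function(object) {
    msg <- character()
    v <- object@counts
    if (nrow(v) != ncol(v)) msg <- c(msg, "counts must be square")
    if (length(object@roiNames) != nrow(v))
      msg <- c(msg, "roiNames length must match matrix dimension")
    if (any(v < 0)) msg <- c(msg, "counts must be non-negative")
    if (max(abs(v - t(v))) > 0) msg <- c(msg, "counts must be symmetric")
    if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
    if (length(object@binariseThreshold) != 1L || object@binariseThreshold < 1)
      msg <- c(msg, "binariseThreshold must be a single value >= 1")
    if (length(msg)) msg else TRUE
  })

#' Set of streamlines in world coordinates
#'
#' Each streamline is an ordered matrix of world-mm points; consecutive
#' points are at most one integration step apart.
#'
#' @slot points list of n x 3 numeric matrices (n >= 1).
#' @slot stepMm integration step used to build them, in mm.
#' @seealso [trackStreamlines()], [streamlineLengths()], [writeTck()]
#' @exportClass StreamlineSet
setClass("StreamlineSet",
  representation(points = "list", stepMm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@stepMm) != 1L || object@stepMm <= 0)
      msg <- c(msg, "stepMm must be a single positive value")
    for (p in object@points)
      if (!is.matrix(p) || ncol(p) != 3L || nrow(p) < 1L) {
        msg <- c(msg, "each streamline must be an n x 3 matrix"); break
      }
    if (length(msg)) msg else TRUE
  })

#' Parameters of the greedy multi-resolution registration
#'
#' Defaults follow common greedy nonlinear-registration practice: a 3-level
#' pyramid (downsampling by 2 per level) with a 30/20/10 iteration schedule
#' run coarse-first, per-iteration updates capped at half a voxel and
#' smoothed (fluid sigma), the accumulated field smoothed (diffusion sigma),
#' and 4 groupwise template iterations.
#'
#' @slot pyramidLevels integer, number of resolution levels.
#' @slot itersPerLevel integer vector, iterations from coarsest to finest.
#' @slot fluidSigma Gaussian sigma (voxels) applied to each update field.
#' @slot diffusionSigma Gaussian sigma (voxels) applied to the total field.
#' @slot maxStep per-iteration displacement cap in voxels.
#' @slot nTemplateIters groupwise template-building iterations.
#' @seealso [registrationParams()], [registerPair()], [buildFunctionalTemplate()]
#' @exportClass RegistrationParams
setClass("RegistrationParams",
  representation(pyramidLevels = "integer", itersPerLevel = "integer",
                 fluidSigma = "numeric", diffusionSigma = "numeric",
                 maxStep = "numeric", nTemplateIters = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@pyramidLevels < 1L) msg <- c(msg, "pyramidLevels must be >= 1")
    if (length(object@itersPerLevel) != object@pyramidLevels ||
        any(object@itersPerLevel < 1L))
      msg <- c(msg, "itersPerLevel must give a positive count per level")
    if (object@fluidSigma < 0 || object@diffusionSigma < 0)
      msg <- c(msg, "smoothing sigmas must be non-negative")
    if (object@maxStep <= 0) msg <- c(msg, "maxStep must be positive")
    if (object@nTemplateIters < 1L) msg <- c(msg, "nTemplateIters must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Result of groupwise functional template construction
#'
#' @slot template the functional-space template map.
#' @slot forwardWarps list of subject-to-template [DisplacementField-class].
#' @slot inverseWarps list of template-to-subject fields.
#' @slot convergence data.frame with one row per template iteration
#'   (iteration, meanNCC).
#' @seealso [buildFunctionalTemplate()], [toGroupSpace()]
#' @exportClass TemplateResult
setClass("TemplateResult",
  representation(template = "ScalarVolume", forwardWarps = "list",
                 inverseWarps = "list", convergence = "data.frame"),
  validity = function(object) {
    if (length(object@forwardWarps) != length(object@inverseWarps))
      "one warp pair per input map required" else TRUE
  })

#' Paired voxelwise sample (two aligned cohorts, same subject order)
#'
#' @slot mapsA,mapsB lists of [ScalarVolume-class] on one grid, equal length.
#' @slot mask logical 3D analysis mask.
#' @seealso [pairedSample()], [pairedTMap()], [permutationFwe()]
#' @exportClass PairedSample
setClass("PairedSample",
  representation(mapsA = "list", mapsB = "list", mask = "array"),
  validity = function(object) {
    msg <- character()
    if (length(object@mapsA) != length(object@mapsB))
      msg <- c(msg, "mapsA and mapsB must pair up (same subject order)")
    if (length(object@mapsA) < 3L) msg <- c(msg, "need at least 3 pairs")
    if (!any(object@mask)) msg <- c(msg, "analysis mask must be non-empty")
    if (length(msg)) msg else TRUE
  })

#' Ground-truth synthetic cohort
#'
#' Everything needed to score the pipeline against a known answer: the
#' ideal network template, the per-subject true warps, the latent network
#' signal parameters, per-subject seed masks, a small atlas of nuclei of
#' very different sizes and a true structural adjacency.
#'
#' @slot template ideal group network map, values in [0, 1].
#' @slot nodeCentres data.frame (name, kind, x, y, z world mm, radiusVox,
#'   amplitude).
#' @slot trueWarps list of per-subject [DisplacementField-class].
#' @slot seedCentres per-subject list of 40 x 3 seed-centre matrices (world mm).
#' @slot snr,rho,T,noiseSd latent-signal parameters.
#' @slot confounds K x T nuisance regressor matrix.
#' @slot atlas [ROISet-class] of synthetic nuclei.
#' @slot trueAdjacency binary node adjacency used for connectome simulation.
#' @slot seed integer RNG seed the cohort was generated from.
#' @seealso [simulateCohort()], [subjectTimeseries()]
#' @exportClass CohortGroundTruth
setClass("CohortGroundTruth",
  representation(template = "ScalarVolume", nodeCentres = "data.frame",
                 trueWarps = "list", seedCentres = "list",
                 snr = "numeric", rho = "numeric", T = "integer",
                 noiseSd = "numeric", confounds = "matrix",
                 atlas = "ROISet", trueAdjacency = "matrix",
                 seed = "integer"))
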