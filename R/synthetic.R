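# Ground-truth synthetic data generators.  Every generator is a pure
# function of its seed: the global RNG state is saved and restored.

withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build an ideal network template from Gaussian blobs
#'
#' Sums isotropic Gaussian blobs (one per network node) and clips to
#' [0, 1].  A blob's `radiusMm` is its support radius: the Gaussian sigma is
#' `radiusMm / 3`, so ~97% of the blob's mass lies within the stated radius
#' and the value at the stated centre is at least 0.99 of its amplitude.
#'
#' @param grid any [VolumeGrid-class] object supplying geometry.
#' @param blobSpec data.frame with columns `x`, `y`, `z` (world mm centre),
#'   `radiusMm` and `amplitude` (in (0, 1]); zero rows give an all-zero
#'   volume.
#' @return a [ScalarVolume-class] with values in [0, 1].
#' @seealso [simulateCohort()] which uses this for the ideal group map.
#' @export
makeTemplate <- function(grid, blobSpec) {
  d <- gridDim(grid)
  out <- array(0, d)
  if (nrow(blobSpec)) {
    if (any(blobSpec$amplitude <= 0 | blobSpec$amplitude > 1))
      stop("amplitudes must be in (0, 1]", call. = FALSE)
    ctrVox <- voxelFromWorld(affine(grid),
                             as.matrix(blobSpec[, c("x", "y", "z")]))
    if (is.null(dim(ctrVox))) ctrVox <- matrix(ctrVox, nrow = 1)
    if (any(ctrVox < 0) || any(ctrVox > matrix(d - 1, nrow(ctrVox), 3,
                                               byrow = TRUE)))
      stop("blob centre outside the grid", call. = FALSE)
    xyz <- worldFromVoxel(affine(grid), gridCoords(d))
    for (b in seq_len(nrow(blobSpec))) {
      sigma <- blobSpec$radiusMm[b] / 3
      d2 <- (xyz[, 1] - blobSpec$x[b])^2 + (xyz[, 2] - blobSpec$y[b])^2 +
            (xyz[, 3] - blobSpec$z[b])^2
      out <- out + array(blobSpec$amplitude[b] * exp(-d2 / (2 * sigma^2)), d)
    }
    out <- pmin(out, 1)
  }
  scalarVolume(out, voxelSize = voxelSize(grid), affine = affine(grid))
}

#' Sample a smooth, invertible subject-specific warp
#'
#' Draws white-noise displacement vectors, smooths each component with a
#' Gaussian of `smoothSigmaVox` voxels (reflect boundaries) and rescales so
#' the maximum displacement norm equals `maxDispVox`.  The precondition
#' `maxDispVox <= 0.4 * smoothSigmaVox` keeps the Jacobian of x + u
#' positive everywhere (diffeomorphic warps).
#'
#' @param grid any [VolumeGrid-class] object.
#' @param maxDispVox maximum displacement in voxels (0 gives a zero field).
#' @param smoothSigmaVox smoothness of the field in voxels.
#' @param seed integer RNG seed; the same seed reproduces the same field.
#' @return a [DisplacementField-class] in voxel units, pull convention.
#' @export
sampleSubjectWarp <- function(grid, maxDispVox, smoothSigmaVox, seed) {
  if (maxDispVox < 0 || smoothSigmaVox <= 0)
    stop("maxDispVox must be >= 0 and smoothSigmaVox > 0", call. = FALSE)
  if (maxDispVox > 0.4 * smoothSigmaVox)
    stop("invertibility margin violated: need maxDispVox <= 0.4 * smoothSigmaVox",
         call. = FALSE)
  d <- gridDim(grid)
  u <- withSeed(seed, array(stats::rnorm(prod(d) * 3), c(d, 3L)))
  if (maxDispVox == 0) {
    u[] <- 0
  } else {
    for (k in 1:3)
      u[, , , k] <- sepGaussSmooth(u[, , , k], rep(smoothSigmaVox, 3))
    n <- sqrt(rowSums(matrix(u, ncol = 3L)^2))
    u <- u * (maxDispVox / max(n))
  }
  displacementField(u, voxelSize = voxelSize(grid), affine = affine(grid))
}

#' Minimum finite-difference Jacobian determinant of x + u
#'
#' Diagnostic used to verify that a sampled warp is diffeomorphic.
#'
#' @param field a [DisplacementField-class].
#' @return the minimum determinant over all voxels (should be > 0).
#' @export
minJacobianDet <- function(field) {
  g <- lapply(1:3, function(k) gradient3(field@vectors[, , , k]))
  J11 <- 1 + g[[1]][, , , 1]; J12 <- g[[1]][, , , 2]; J13 <- g[[1]][, , , 3]
  J21 <- g[[2]][, , , 1]; J22 <- 1 + g[[2]][, , , 2]; J23 <- g[[2]][, , , 3]
  J31 <- g[[3]][, , , 1]; J32 <- g[[3]][, , , 2]; J33 <- 1 + g[[3]][, , , 3]
  det <- J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
         J13 * (J21 * J32 - J22 * J31)
  min(det)
}

#' Simulate a BOLD-like time series from a subject template
#'
#' Each voxel's series is `template(v) * s(t)` plus optional confound
#' components and i.i.d. Gaussian noise, where `s` is a standardised AR(1)
#' latent network signal (lag-1 autocorrelation `rho`, mimicking BOLD
#' autocorrelation).  The noise standard deviation is `1 / snr`, so a voxel
#' with template value 1 has theoretical correlation
#' `snr / sqrt(1 + snr^2)` with the latent signal.
#'
#' @param subjectTemplate a [ScalarVolume-class] of network loadings.
#' @param T number of time points (>= 30).
#' @param snr positive signal-to-noise ratio at template value 1.
#' @param confounds optional K x T matrix of nuisance time courses; each
#'   voxel receives them with independent N(0, 0.5^2) loadings.
#' @param rho AR(1) coefficient of the latent signal (default 0.3).
#' @param seed integer RNG seed.
#' @return a [TimeSeriesVolume-class]; the latent signal is attached as
#'   attribute `"latentSignal"`.
#' @export
simulateTimeseries <- function(subjectTemplate, T, snr, confounds = NULL,
                               rho = 0.3, seed = 1L) {
  if (T < 30) stop("need T >= 30", call. = FALSE)
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  d <- gridDim(subjectTemplate)
  V <- prod(d)
  tv <- as.vector(subjectTemplate@data)
  arr <- withSeed(seed, {
    s <- as.vector(stats::arima.sim(list(ar = rho), T))
    s <- as.vector(scale(s))
    Y <- outer(tv, s)
    if (!is.null(confounds)) {
      stopifnot(ncol(confounds) == T)
      L <- matrix(stats::rnorm(V * nrow(confounds), sd = 0.5), V)
      Y <- Y + L %*% confounds
    }
    Y <- Y + matrix(stats::rnorm(V * T, sd = 1 / snr), V)
    attr(Y, "s") <- s
    Y
  })
  out <- timeSeriesVolume(array(arr, c(d, T)),
                          voxelSize = voxelSize(subjectTemplate),
                          affine = affine(subjectTemplate))
  attr(out, "latentSignal") <- attr(arr, "s")
  out
}

#' Simulate per-subject streamline-count connectomes
#'
#' Draws each upper-triangular cell from Poisson(meanCount * adjacency) and
#' mirrors it, giving symmetric non-negative counts with zero diagonal.
#'
#' @param trueAdjacency symmetric 0/1 matrix with zero diagonal.
#' @param meanCount positive Poisson mean for true edges.
#' @param nSubjects number of subjects.
#' @param seed integer RNG seed.
#' @return list of `nSubjects` count matrices.
#' @seealso [binarizeConnectome()], [graphMetrics()]
#' @export
simulateConnectome <- function(trueAdjacency, meanCount, nSubjects, seed) {
  if (meanCount <= 0) stop("meanCount must be positive", call. = FALSE)
  A <- trueAdjacency
  if (!isTRUE(all.equal(A, t(A))) || any(diag(A) != 0))
    stop("adjacency must be symmetric with zero diagonal", call. = FALSE)
  n <- nrow(A)
  up <- upper.tri(A)
  withSeed(seed, lapply(seq_len(nSubjects), function(i) {
    M <- matrix(0, n, n, dimnames = dimnames(A))
    M[up] <- stats::rpois(sum(up), meanCount * A[up])
    M + t(M)
  }))
}

#' Build a small synthetic atlas of spherical nuclei
#'
#' Each nucleus is the set of voxels whose centre lies within `radiusMm` of
#' the stated world-mm centre; a radius smaller than half a voxel still
#' yields the single voxel containing the centre.  For radii of at least 3
#' voxels the voxel count is within 10% of the analytic sphere volume.
#'
#' @param grid any [VolumeGrid-class] object.
#' @param nucleiSpec data.frame with columns `name`, `x`, `y`, `z` (world
#'   mm) and `radiusMm` (> 0); names must be unique.
#' @return a [ROISet-class] with provenance `"user-supplied"`.
#' @export
makeAtlas <- function(grid, nucleiSpec) {
  if (anyDuplicated(nucleiSpec$name))
    stop("duplicate nucleus names", call. = FALSE)
  if (any(nucleiSpec$radiusMm <= 0))
    stop("radii must be positive", call. = FALSE)
  d <- gridDim(grid)
  xyz <- worldFromVoxel(affine(grid), gridCoords(d))
  masks <- lapply(seq_len(nrow(nucleiSpec)), function(i) {
    d2 <- (xyz[, 1] - nucleiSpec$x[i])^2 + (xyz[, 2] - nucleiSpec$y[i])^2 +
          (xyz[, 3] - nucleiSpec$z[i])^2
    m <- array(d2 <= nucleiSpec$radiusMm[i]^2, d)
    if (!any(m)) m[arrayInd(which.min(d2), d)] <- TRUE
    m
  })
  names(masks) <- nucleiSpec$name
  roiSet(masks, provenance = "user-supplied",
         voxelSize = voxelSize(grid), affine = affine(grid))
}
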