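#' Regress nuisance confounds out of a time-series volume
#'
#' Ordinary least squares per voxel on a design of intercept, the supplied
#' confound time courses and (optionally) their first derivatives, computed
#' by linear convolution with a (-1, 0, 1) vector as is conventional for
#' motion and physiological regressors.  Rank-deficient designs drop the
#' dependent columns with a warning.  Residuals are orthogonal to every
#' retained regressor.
#'
#' @param ts a [TimeSeriesVolume-class].
#' @param confounds K x T numeric matrix (K < T), or NULL for
#'   intercept-only (demeaning).
#' @param addDerivatives add first temporal derivatives of the confounds.
#' @return the residual [TimeSeriesVolume-class].
#' @export
regressConfounds <- function(ts, confounds = NULL, addDerivatives = FALSE) {
  T <- nTimepoints(ts)
  X <- matrix(1, T, 1)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) >= T && ncol(confounds) == T)
      stop("confounds must be K x T with K < T", call. = FALSE)
    if (ncol(confounds) != T)
      stop("confounds must have one column per time point", call. = FALSE)
    if (any(!is.finite(confounds)))
      stop("confound columns must be finite", call. = FALSE)
    X <- cbind(X, t(confounds))
    if (addDerivatives) {
      der <- t(apply(confounds, 1, function(cc) {
        # central difference: convolution of the series with (-1, 0, 1)
        c(cc[2] - cc[1], (cc[-(1:2)] - cc[-((T - 1):T)]) / 2,
          cc[T] - cc[T - 1])
      }))
      X <- cbind(X, t(der))
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient confound design: dropped ",
            ncol(X) - qrX$rank, " dependent column(s)", call. = FALSE)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  d <- dim(ts@data)
  Y <- t(matrix(ts@data, prod(d[1:3]), d[4]))  # T x V
  res <- qr.resid(qrX, Y)
  timeSeriesVolume(array(t(res), d), voxelSize = ts@voxelSize,
                   affine = ts@affine)
}

#' First eigenvariate of the series inside a mask
#'
#' The first principal component of the voxel series within `mask`
#' (singular vector of the centred T x V data), sign-fixed so that its
#' correlation with the mean masked series is non-negative.  This is the
#' conventional summary used for white-matter and CSF nuisance signals.
#'
#' @param ts a [TimeSeriesVolume-class].
#' @param mask logical/0-1 3D array.
#' @return numeric vector of length T.
#' @export
maskEigenvariate <- function(ts, mask) {
  idx <- which(mask > 0)
  if (!length(idx)) stop("mask is empty", call. = FALSE)
  d <- dim(ts@data)
  Y <- matrix(ts@data, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  Yc <- t(Y) - colMeans(t(Y))           # centre each voxel's series
  e <- svd(Yc, nu = 1, nv = 0)$u[, 1]
  m <- colMeans(Y)
  if (stats::sd(m) > 0 && stats::cor(e, m) < 0) e <- -e
  e
}

#' Seed-based Pearson correlation map
#'
#' Correlates the mean time course of the seed mask with every voxel's
#' series.  Voxels with zero variance get r = 0; their count is attached as
#' attribute `"nZeroVariance"` (masked-out background is ubiquitous and is
#' not an error).
#'
#' @param ts a [TimeSeriesVolume-class] (T >= 3).
#' @param seed logical/0-1 3D array, non-empty.
#' @return a [ScalarVolume-class] of correlations in [-1, 1].
#' @export
seedCorrelationMap <- function(ts, seed) {
  idx <- which(seed > 0)
  if (!length(idx)) stop("seed mask is empty", call. = FALSE)
  d <- dim(ts@data)
  if (d[4] < 3L) stop("need at least 3 time points", call. = FALSE)
  Y <- matrix(ts@data, prod(d[1:3]), d[4])
  s <- colMeans(Y[idx, , drop = FALSE])
  r <- corWithVector(Y, s)
  out <- scalarVolume(array(r$r, d[1:3]), voxelSize = ts@voxelSize,
                      affine = ts@affine)
  attr(out, "nZeroVariance") <- r$nZero
  out
}

# correlation of every row of V x T matrix Y with time course s;
# zero-variance rows (or a zero-variance s) give r = 0
corWithVector <- function(Y, s) {
  T <- length(s)
  sc <- s - mean(s)
  ss <- sqrt(sum(sc^2))
  mY <- rowMeans(Y)
  num <- as.vector(Y %*% sc)            # sum(yc * sc) since sum(sc) = 0
  den <- sqrt(pmax(rowSums(Y^2) - T * mY^2, 0))
  bad <- den < (sqrt(T) * 1e-12 + 1e-300) | ss == 0
  r <- numeric(nrow(Y))
  ok <- !bad
  r[ok] <- num[ok] / (den[ok] * ss)
  r <- pmin(1, pmax(-1, r))
  list(r = r, nZero = sum(bad))
}

#' Individual DMN map: voxelwise median over per-seed correlation maps
#'
#' Computes one correlation map per seed and takes the voxelwise median
#' across seeds (an even number of seeds uses the midpoint of the two
#' central order statistics).  The median makes the map robust to an
#' outlying seed.
#'
#' @param ts a [TimeSeriesVolume-class].
#' @param seeds a [ROISet-class] of seed masks (e.g. 40 network nodes).
#' @return a [ScalarVolume-class]; attribute `"nZeroVariance"` carries the
#'   per-seed zero-variance voxel counts.
#' @export
individualDmnMap <- function(ts, seeds) {
  if (length(seeds@masks) < 1L) stop("need at least one seed", call. = FALSE)
  d <- dim(ts@data)
  Y <- matrix(ts@data, prod(d[1:3]), d[4])
  nz <- integer(length(seeds@masks))
  R <- matrix(0, nrow(Y), length(seeds@masks))
  for (j in seq_along(seeds@masks)) {
    idx <- which(seeds@masks[[j]] > 0)
    if (!length(idx)) stop("seed mask is empty: ", names(seeds@masks)[j],
                           call. = FALSE)
    res <- corWithVector(Y, colMeans(Y[idx, , drop = FALSE]))
    R[, j] <- res$r
    nz[j] <- res$nZero
  }
  out <- scalarVolume(array(rowMedians_(R), d[1:3]),
                      voxelSize = ts@voxelSize, affine = ts@affine)
  attr(out, "nZeroVariance") <- stats::setNames(nz, names(seeds@masks))
  out
}

#' Voxelwise median across subject maps
#'
#' The group map: median of the per-subject maps at each voxel, with the
#' same even-count midpoint rule as [individualDmnMap()].
#'
#' @param maps list of at least two [ScalarVolume-class] on one grid.
#' @return a [ScalarVolume-class].
#' @export
groupMedianMap <- function(maps) {
  if (length(maps) < 2L) stop("need at least 2 maps", call. = FALSE)
  for (m in maps[-1]) stopIfDifferentGrid(maps[[1]], m, "maps")
  X <- vapply(maps, function(m) as.vector(m@data),
              numeric(prod(gridDim(maps[[1]]))))
  scalarVolume(array(rowMedians_(X), gridDim(maps[[1]])),
               voxelSize = maps[[1]]@voxelSize, affine = maps[[1]]@affine)
}
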