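#' Construct a paired voxelwise sample
#'
#' @param mapsA,mapsB per-subject [ScalarVolume-class] lists in the same
#'   subject order (>= 3 pairs).
#' @param mask logical analysis mask; defaults to all voxels.
#' @return a [PairedSample-class].
#' @export
pairedSample <- function(mapsA, mapsB, mask = NULL) {
  stopifnot(length(mapsA) == length(mapsB))
  for (m in c(mapsA, mapsB))
    stopIfDifferentGrid(mapsA[[1]], m, "paired maps")
  if (is.null(mask)) mask <- array(TRUE, gridDim(mapsA[[1]]))
  new("PairedSample", mapsA = mapsA, mapsB = mapsB, mask = mask & TRUE)
}

# n x V matrix of paired differences over the mask
pairedDiffMatrix <- function(sample) {
  idx <- which(sample@mask)
  m <- vapply(seq_along(sample@mapsA), function(i)
    as.vector(sample@mapsA[[i]]@data)[idx] -
      as.vector(sample@mapsB[[i]]@data)[idx],
    numeric(length(idx)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(idx))
  t(m)
}

# vectorised one-sample t on the columns of an n x V matrix;
# zero-variance columns get t = 0
colT <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- numeric(ncol(D))
  ok <- v > 1e-24
  t[ok] <- m[ok] / sqrt(v[ok] / n)
  attr(t, "zeroVar") <- !ok
  t
}

#' Voxelwise subtraction of two group maps
#'
#' @param mapA,mapB [ScalarVolume-class] on one grid.
#' @return `mapA - mapB` as a [ScalarVolume-class].
#' @export
subtractGroupMaps <- function(mapA, mapB) {
  stopIfDifferentGrid(mapA, mapB, "maps")
  scalarVolume(mapA@data - mapB@data, voxelSize = mapA@voxelSize,
               affine = mapA@affine)
}

#' Voxelwise paired t-map
#'
#' Per-voxel paired t statistic on the differences d = a - b:
#' t = mean(d) / (sd(d) / sqrt(n)).  Voxels with zero difference variance
#' get t = 0 and are flagged (attribute `"nZeroVariance"`); they are
#' excluded from permutation inference.
#'
#' @param sample a [PairedSample-class] with n >= 3 pairs.
#' @return a [ScalarVolume-class] of t values (0 outside the mask).
#' @export
pairedTMap <- function(sample) {
  D <- pairedDiffMatrix(sample)
  t <- colT(D)
  d <- gridDim(sample@mapsA[[1]])
  out <- array(0, d)
  out[which(sample@mask)] <- t
  res <- scalarVolume(out, voxelSize = sample@mapsA[[1]]@voxelSize,
                      affine = sample@mapsA[[1]]@affine)
  attr(res, "nZeroVariance") <- sum(attr(t, "zeroVar"))
  res
}

# family-wise-error corrected p-values by sign-flip max-|t| permutation.
# D: n x V differences.  Returns list(t, p, maxDist).
signFlipFwe <- function(D, nPerm, seed, varSmoothFun = NULL,
                        errorOnAllZeroVar = TRUE,
                        method = c("auto", "sampled", "exhaustive")) {
  method <- match.arg(method)
  n <- nrow(D); V <- ncol(D)
  tFun <- function(M, signs = NULL) {
    # t for each permutation row of the B x V mean matrix
    if (is.null(signs)) return(colT(M))
    mean_ <- (signs %*% M) / n                     # B x V
    ssq <- matrix(colSums(M^2), nrow(signs), V, byrow = TRUE)
    v <- (ssq - n * mean_^2) / (n - 1)
    v[v < 0] <- 0
    if (!is.null(varSmoothFun)) v <- t(apply(v, 1, varSmoothFun))
    tt <- mean_ / sqrt(v / n)
    tt[!is.finite(tt)] <- 0
    tt
  }
  if (is.null(varSmoothFun)) {
    tObs <- colT(D)
    zeroVar <- attr(tObs, "zeroVar")
  } else {
    m <- colMeans(D)
    v <- (colSums(D^2) - n * m^2) / (n - 1)
    v[v < 0] <- 0
    vs <- varSmoothFun(v)
    # smoothing borrows variance from neighbours, so only voxels whose
    # smoothed variance is still zero are uninformative
    zeroVar <- vs <= 1e-24
    tObs <- ifelse(!zeroVar, m / sqrt(vs / n), 0)
  }
  if (all(zeroVar)) {
    if (max(abs(D)) == 0 || !errorOnAllZeroVar) {
      if (max(abs(D)) > 0)
        warning("zero variance at every voxel: no permutation inference",
                call. = FALSE)
      return(list(t = tObs, p = rep(1, V), maxDist = numeric()))
    }
    stop("zero variance at every voxel", call. = FALSE)
  }
  exhaustive <- switch(method, auto = 2^n <= nPerm, sampled = FALSE,
                       exhaustive = TRUE)
  if (method == "exhaustive" && n > 20)
    stop("exhaustive enumeration is limited to n <= 20", call. = FALSE)
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    B <- nrow(signs)
  } else {
    signs <- withSeed(seed, matrix(sample(c(-1, 1), nPerm * n, replace = TRUE),
                                   nPerm, n))
    B <- nPerm
  }
  live <- which(!zeroVar)
  Dl <- D[, live, drop = FALSE]
  maxDist <- numeric(B)
  chunk <- max(1L, floor(2e6 / max(length(live), 1L)))
  for (st in seq(1L, B, by = chunk)) {
    en <- min(st + chunk - 1L, B)
    tt <- tFun(Dl, signs[st:en, , drop = FALSE])
    maxDist[st:en] <- apply(abs(tt), 1, max)
  }
  p <- rep(1, V)
  srt <- sort(maxDist)
  nGe <- B - findInterval(abs(tObs[live]) - 1e-12, srt)
  p[live] <- if (exhaustive) nGe / B else (1 + nGe) / (B + 1)
  list(t = tObs, p = p, maxDist = maxDist)
}

#' Permutation family-wise error correction for a paired comparison
#'
#' Sign-flipping of the paired differences with the maximum-|t| null: the
#' corrected p at voxel v is (1 + #permutations whose max |t*| over the
#' mask is >= |t(v)|) / (nPerm + 1).  When 2^n <= nPerm all sign patterns
#' are enumerated exhaustively (and the +1 correction is dropped since the
#' null is exact).  Deterministic given `seed`.  Zero-variance voxels are
#' excluded from inference and get p = 1.
#'
#' @param sample a [PairedSample-class] (n >= 5 recommended).
#' @param nPerm number of sign-flip permutations (< 100 raises a warning).
#' @param seed integer RNG seed.
#' @param method `"auto"` (exhaustive when 2^n <= nPerm, else sampled),
#'   or force `"sampled"` / `"exhaustive"`.
#' @return list with `t` and `p` ([ScalarVolume-class], corrected p; 1
#'   outside the mask) and `maxDist`, the permutation distribution of the
#'   maximum |t|.
#' @export
permutationFwe <- function(sample, nPerm = 1000L, seed = 1L,
                           method = c("auto", "sampled", "exhaustive")) {
  if (nPerm < 100) warning("fewer than 100 permutations gives a very coarse ",
                           "p-value resolution", call. = FALSE)
  D <- pairedDiffMatrix(sample)
  res <- signFlipFwe(D, nPerm, seed, method = match.arg(method))
  d <- gridDim(sample@mapsA[[1]])
  idx <- which(sample@mask)
  tArr <- array(0, d); tArr[idx] <- res$t
  pArr <- array(1, d); pArr[idx] <- res$p
  vs <- sample@mapsA[[1]]@voxelSize; af <- sample@mapsA[[1]]@affine
  list(t = scalarVolume(tArr, voxelSize = vs, affine = af),
       p = scalarVolume(pArr, voxelSize = vs, affine = af),
       maxDist = res$maxDist)
}

#' Cluster table of a corrected statistical map
#'
#' Thresholds the corrected p-map at `alpha` (strict <), labels
#' suprathreshold voxels by 26-connectivity, and reports per cluster the
#' voxel count, the minimum corrected p, the paired Cohen's d
#' (mean(d)/sd(d)) at the peak-|t| voxel, and the |t|-weighted centre of
#' gravity in world mm.
#'
#' @param pMap corrected p [ScalarVolume-class] (from [permutationFwe()]).
#' @param tMap matching t [ScalarVolume-class].
#' @param sample the [PairedSample-class] the maps came from.
#' @param alpha corrected significance level in (0, 1).
#' @return data.frame with columns clusterIndex, voxels, pMin, effectSize,
#'   x, y, z; zero rows when nothing survives.
#' @export
clusterTable <- function(pMap, tMap, sample, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  supra <- pMap@data < alpha
  empty <- data.frame(clusterIndex = integer(), voxels = integer(),
                      pMin = numeric(), effectSize = numeric(),
                      x = numeric(), y = numeric(), z = numeric())
  if (!any(supra)) return(empty)
  lab <- connComp26(supra)
  K <- max(lab)
  D <- pairedDiffMatrix(pairedSample(sample@mapsA, sample@mapsB,
                                     array(TRUE, gridDim(pMap))))
  rows <- lapply(seq_len(K), function(k) {
    idx <- which(lab == k)
    tv <- abs(tMap@data[idx])
    peak <- idx[which.max(tv)]
    dPeak <- D[, peak]
    es <- if (stats::sd(dPeak) > 0) mean(dPeak) / stats::sd(dPeak) else NA_real_
    w <- tv / sum(tv)
    cogVox <- colSums((arrayInd(idx, gridDim(pMap)) - 1) * w)
    cog <- worldFromVoxel(pMap@affine, cogVox)
    data.frame(clusterIndex = k, voxels = length(idx),
               pMin = min(pMap@data[idx]), effectSize = es,
               x = cog[1], y = cog[2], z = cog[3])
  })
  do.call(rbind, rows)
}

#' One-sample t-map with variance smoothing and sign-flip inference
#'
#' The one-sample t-test used for binarised tract visitation maps: the
#' voxelwise variance image is Gaussian-smoothed (sigma in mm) before
#' forming t = mean / sqrt(var_smoothed / n), which stabilises variance
#' estimates for near-binary data; `smoothSigmaMm = 0` reduces to the
#' ordinary one-sample t.  Family-wise error correction uses the same
#' sign-flip maximum-statistic scheme as [permutationFwe()], with the
#' variance re-smoothed inside every permutation.
#'
#' @param maps list of per-subject [ScalarVolume-class] (n >= 5).
#' @param smoothSigmaMm variance-smoothing sigma in mm (default 4).
#' @param nPerm permutations for the corrected p-map.
#' @param seed integer RNG seed.
#' @param mask optional logical analysis mask.
#' @return list with `t`, `p` ([ScalarVolume-class]) and `maxDist`.
#' @export
oneSampleTMapVarSmooth <- function(maps, smoothSigmaMm = 4, nPerm = 1000L,
                                   seed = 1L, mask = NULL) {
  if (length(maps) < 5L) stop("need at least 5 maps", call. = FALSE)
  for (m in maps[-1]) stopIfDifferentGrid(maps[[1]], m, "maps")
  d <- gridDim(maps[[1]])
  if (is.null(mask)) mask <- array(TRUE, d)
  idx <- which(mask)
  D <- t(vapply(maps, function(m) as.vector(m@data)[idx],
                numeric(length(idx))))
  sigVox <- smoothSigmaMm / maps[[1]]@voxelSize
  varSmoothFun <- if (smoothSigmaMm > 0) {
    function(v) {
      arr <- array(0, d); arr[idx] <- v
      pmax(sepGaussSmooth(arr, sigVox)[idx], 0)
    }
  } else NULL
  res <- signFlipFwe(D, nPerm, seed, varSmoothFun = varSmoothFun,
                     errorOnAllZeroVar = FALSE)
  tArr <- array(0, d); tArr[idx] <- res$t
  pArr <- array(1, d); pArr[idx] <- res$p
  vs <- maps[[1]]@voxelSize; af <- maps[[1]]@affine
  list(t = scalarVolume(tArr, voxelSize = vs, affine = af),
       p = scalarVolume(pArr, voxelSize = vs, affine = af),
       maxDist = res$maxDist)
}
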