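#' Construct a ROISet
#'
#' @param masks named list of logical 3D arrays on one grid.
#' @param provenance `"thresholded-component"` or `"user-supplied"`;
#'   overlapping masks are tolerated (with a warning) only for
#'   user-supplied sets.
#' @param voxelSize,affine grid geometry (taken from `reference` if given).
#' @param reference optional [VolumeGrid-class] supplying the geometry.
#' @return a [ROISet-class].
#' @export
roiSet <- function(masks, provenance = "user-supplied",
                   voxelSize = c(1, 1, 1), affine = NULL, reference = NULL) {
  if (!is.null(reference)) {
    voxelSize <- voxelSize(reference); affine <- affine(reference)
  }
  if (is.null(affine)) { affine <- diag(4); diag(affine)[1:3] <- voxelSize }
  masks <- lapply(masks, function(m) m > 0)
  obj <- new("ROISet", masks = masks, provenance = provenance,
             voxelSize = as.numeric(voxelSize), affine = affine)
  if (length(masks) > 1L) {
    tot <- Reduce(`+`, masks)
    if (any(tot > 1)) {
      if (provenance == "thresholded-component")
        stop("thresholded-component masks must not overlap", call. = FALSE)
      warning("user-supplied masks overlap at ", sum(tot > 1), " voxel(s)",
              call. = FALSE)
    }
  }
  obj
}

#' @rdname roi-accessors
#' @export
setMethod("roiNames", "ROISet", function(x) names(x@masks))
#' @rdname roi-accessors
#' @export
setMethod("roiNames", "CorrelationMatrix", function(x) x@roiNames)
#' @rdname roi-accessors
#' @export
setMethod("roiNames", "Connectome", function(x) x@roiNames)

setMethod("show", "ROISet", function(object) {
  cat("ROISet (", object@provenance, "): ", length(object@masks),
      " masks on a ", paste(gridDim(object), collapse = " x "), " grid\n",
      sep = "")
})

#' Extract regions of interest from a thresholded group map
#'
#' Labels voxels with connectivity strictly above `rThreshold` by
#' 26-connectivity; any component that straddles the world x = 0 plane is
#' split into left (x < 0) and right (x >= 0) parts, reflecting bilateral
#' homologues that merge across the midline.  User-supplied masks (e.g.
#' manually delineated subcortical regions) are appended and take
#' precedence over same-named components.
#'
#' @param groupMap a [ScalarVolume-class] group connectivity map.
#' @param rThreshold threshold in (0, 1); strictly-greater-than rule.
#' @param manualMasks optional named list of logical masks to append.
#' @return a [ROISet-class]; see [roiSummary()] for counts and centres.
#' @export
extractRois <- function(groupMap, rThreshold = 0.3, manualMasks = NULL) {
  stopifnot(rThreshold > 0, rThreshold < 1)
  supra <- groupMap@data > rThreshold
  if (!any(supra)) stop("no voxels above the threshold", call. = FALSE)
  lab <- connComp26(supra)
  d <- gridDim(groupMap)
  worldX <- array(worldFromVoxel(groupMap@affine, gridCoords(d))[, 1], d)
  masks <- list()
  for (k in seq_len(max(lab))) {
    mk <- lab == k
    xs <- worldX[mk]
    nm <- sprintf("comp%02d", k)
    if (any(xs < 0) && any(xs >= 0)) {
      masks[[paste0(nm, "_L")]] <- mk & (worldX < 0)
      masks[[paste0(nm, "_R")]] <- mk & (worldX >= 0)
    } else masks[[nm]] <- mk
  }
  prov <- "thresholded-component"
  if (!is.null(manualMasks)) {
    for (nm in names(manualMasks)) masks[[nm]] <- manualMasks[[nm]] > 0
    prov <- "user-supplied"
  }
  roiSet(masks, provenance = prov, reference = groupMap)
}

#' Per-ROI voxel counts and centres of gravity
#'
#' @param rois a [ROISet-class].
#' @return data.frame with name, voxels, and unweighted centre of gravity
#'   in world mm (x, y, z).
#' @export
roiSummary <- function(rois) {
  d <- gridDim(rois)
  rows <- lapply(names(rois@masks), function(nm) {
    idx <- which(rois@masks[[nm]])
    cog <- worldFromVoxel(rois@affine, colMeans(arrayInd(idx, d)) - 1)
    data.frame(name = nm, voxels = length(idx),
               x = cog[1], y = cog[2], z = cog[3])
  })
  do.call(rbind, rows)
}

#' Mean time series per region of interest
#'
#' Unweighted mean over the mask voxels at each time point.
#'
#' @param ts a [TimeSeriesVolume-class].
#' @param rois a [ROISet-class] on the same grid.
#' @return T x n matrix with one named column per ROI.
#' @export
roiMeanTimeseries <- function(ts, rois) {
  stopIfDifferentGrid(ts, rois, "series and ROIs")
  d <- dim(ts@data)
  Y <- matrix(ts@data, prod(d[1:3]), d[4])
  out <- vapply(rois@masks, function(m) {
    idx <- which(m)
    if (!length(idx)) stop("empty ROI mask", call. = FALSE)
    colMeans(Y[idx, , drop = FALSE])
  }, numeric(d[4]))
  colnames(out) <- names(rois@masks)
  out
}

#' Full Pearson correlation matrix of ROI time series
#'
#' @param roiTs T x n matrix of ROI mean series (named columns).
#' @return a [CorrelationMatrix-class] of kind `"full"`.
#' @export
correlationMatrix <- function(roiTs) {
  n <- ncol(roiTs)
  sds <- apply(roiTs, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance ROI series: ",
         paste(colnames(roiTs)[sds == 0], collapse = ", "), call. = FALSE)
  if (nrow(roiTs) < n + 2)
    warning("fewer time points than n + 2; correlations will be unstable",
            call. = FALSE)
  R <- stats::cor(roiTs)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  new("CorrelationMatrix", values = R,
      roiNames = colnames(roiTs) %||% sprintf("roi%02d", seq_len(n)),
      kind = "full")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partial correlation matrix via precision inversion
#'
#' Inverts the full correlation matrix R (adding the smallest ridge
#' lambda * I, lambda stepping by decades from 1e-8, whenever the condition
#' number exceeds 1e8) and maps the precision P to partial correlations
#' rho_ij = -P_ij / sqrt(P_ii P_jj), the correlation of each pair after
#' regressing out all other regions.  The diagonal is fixed to 1 by
#' convention.  The ridge actually used is attached as attribute
#' `"ridge"`.
#'
#' @param roiTs T x n matrix of ROI mean series, or a
#'   [CorrelationMatrix-class] of kind `"full"`.
#' @return a [CorrelationMatrix-class] of kind `"partial"`.
#' @export
partialCorrelationMatrix <- function(roiTs) {
  R <- if (is(roiTs, "CorrelationMatrix")) roiTs@values
       else correlationMatrix(roiTs)@values
  nm <- if (is(roiTs, "CorrelationMatrix")) roiTs@roiNames
        else colnames(roiTs) %||% sprintf("roi%02d", seq_len(ncol(R)))
  lambda <- 0
  repeat {
    Rr <- R + diag(lambda, nrow(R))
    k <- tryCatch(kappa(Rr, exact = TRUE), error = function(e) Inf)
    if (is.finite(k) && k <= 1e8) break
    lambda <- if (lambda == 0) 1e-8 else lambda * 10
    if (lambda > 0.1)
      stop("correlation matrix not invertible even at ridge 0.1",
           call. = FALSE)
  }
  P <- solve(Rr)
  s <- 1 / sqrt(diag(P))
  rho <- -P * outer(s, s)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  rho[] <- pmin(1, pmax(-1, rho))
  out <- new("CorrelationMatrix", values = rho, roiNames = nm,
             kind = "partial")
  attr(out, "ridge") <- lambda
  out
}

setMethod("show", "CorrelationMatrix", function(object) {
  off <- object@values[lower.tri(object@values)]
  cat("CorrelationMatrix (", object@kind, "), ", length(object@roiNames),
      " regions; off-diagonal range ",
      paste(signif(range(off), 3), collapse = " .. "), "\n", sep = "")
})

#' Bonferroni per-comparison threshold for all unique region pairs
#'
#' With n regions there are m = n(n-1)/2 unique off-diagonal cells; the
#' per-comparison level is familyAlpha / m (for 33 regions and family
#' alpha 0.05: 0.05 / 528 = 9.4697e-5, below the 1e-4 level).
#'
#' @param nRoi number of regions.
#' @param familyAlpha family-wise alpha (default 0.05).
#' @return the per-comparison alpha.
#' @examples
#' bonferroniThreshold(33)
#' @export
bonferroniThreshold <- function(nRoi, familyAlpha = 0.05) {
  familyAlpha / (nRoi * (nRoi - 1) / 2)
}

fisherZ <- function(r) atanh(pmax(pmin(r, 1 - 1e-10), -1 + 1e-10))

# stack unique off-diagonal cells of per-subject matrices: S x m
cellMatrix <- function(mats) {
  up <- upper.tri(mats[[1]]@values)
  t(vapply(mats, function(m) m@values[up], numeric(sum(up))))
}

#' Cellwise tests on per-subject connectivity matrices
#'
#' Fisher z-transforms every unique off-diagonal cell (correlations at
#' |r| = 1 are clipped before the transform) and runs, per cell, a paired
#' t-test between conditions a and b and one-sample t-tests against zero
#' within each condition, at the Bonferroni per-comparison level
#' familyAlpha / m with m = n(n-1)/2.  Also reports per-cell median, range
#' and interquartile summaries of the raw correlations.
#'
#' @param matsA,matsB lists of per-subject [CorrelationMatrix-class]
#'   objects in the same subject order (>= 3 subjects).
#' @param familyAlpha family-wise alpha (default 0.05).
#' @return list with `paired` and `oneSampleA`/`oneSampleB` data.frames
#'   (roiI, roiJ, t, p, significant), `threshold`, and
#'   `fractionSignificantPaired`.
#' @export
matrixTests <- function(matsA, matsB, familyAlpha = 0.05) {
  stopifnot(length(matsA) == length(matsB), length(matsA) >= 3L)
  n <- length(matsA[[1]]@roiNames)
  thr <- bonferroniThreshold(n, familyAlpha)
  ZA <- fisherZ(cellMatrix(matsA))
  ZB <- fisherZ(cellMatrix(matsB))
  up <- which(upper.tri(matsA[[1]]@values), arr.ind = TRUE)
  nm <- matsA[[1]]@roiNames
  S <- nrow(ZA)
  cellTest <- function(D) {
    t <- colT(D)
    p <- 2 * stats::pt(abs(t), df = S - 1, lower.tail = FALSE)
    p[attr(t, "zeroVar")] <- 1
    data.frame(roiI = nm[up[, 1]], roiJ = nm[up[, 2]], t = as.vector(t),
               p = p, significant = p < thr)
  }
  paired <- cellTest(ZA - ZB)
  rawA <- cellMatrix(matsA)
  summ <- data.frame(roiI = nm[up[, 1]], roiJ = nm[up[, 2]],
                     median = apply(rawA, 2, stats::median),
                     min = apply(rawA, 2, min), max = apply(rawA, 2, max),
                     q25 = apply(rawA, 2, pctl, 0.25),
                     q75 = apply(rawA, 2, pctl, 0.75))
  list(paired = paired, oneSampleA = cellTest(ZA), oneSampleB = cellTest(ZB),
       summaryA = summ, threshold = thr,
       fractionSignificantPaired = mean(paired$significant))
}
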