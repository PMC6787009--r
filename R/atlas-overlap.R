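#' Binarise a connectivity map at the analysis threshold
#'
#' Strictly-greater-than binarisation, the one thresholding rule used
#' throughout the pipeline (a voxel at exactly the threshold is excluded).
#'
#' @param map a [ScalarVolume-class].
#' @param rThreshold threshold in (0, 1), default 0.3.
#' @return a binary [ScalarVolume-class].
#' @export
dmnMask <- function(map, rThreshold = 0.3) {
  stopifnot(rThreshold > 0, rThreshold < 1)
  scalarVolume((map@data > rThreshold) + 0, voxelSize = map@voxelSize,
               affine = map@affine)
}

#' Subject-density map
#'
#' Percentage of subjects whose binary mask covers each voxel.
#'
#' @param subjectMasks list of binary [ScalarVolume-class] on one grid.
#' @return a [ScalarVolume-class] with values in [0, 100].
#' @export
densityMap <- function(subjectMasks) {
  if (length(subjectMasks) < 1L) stop("need at least one mask", call. = FALSE)
  for (m in subjectMasks[-1])
    stopIfDifferentGrid(subjectMasks[[1]], m, "masks")
  acc <- Reduce(`+`, lapply(subjectMasks, function(m) (m@data > 0) + 0))
  scalarVolume(100 * acc / length(subjectMasks),
               voxelSize = subjectMasks[[1]]@voxelSize,
               affine = subjectMasks[[1]]@affine)
}

#' Overlap statistics between subject masks and one atlas nucleus
#'
#' Per subject, the intersection voxel count with the nucleus, the
#' percentage of the nucleus volume covered and the absolute intersection
#' volume; aggregated as the percentage of subjects with any intersection
#' and the median [25th-75th percentile] of the per-subject percentage and
#' absolute volumes.
#'
#' @param subjectMasks list of binary [ScalarVolume-class] in group space.
#' @param nucleusMask logical/0-1 3D array (non-empty) or binary
#'   [ScalarVolume-class]; probabilistic maps should be binarised first
#'   (e.g. at 0.5).
#' @param voxelVolumeMm3 volume of one voxel in mm^3; defaults to the
#'   product of the subject masks' voxel size.
#' @return one-row data.frame (Table-3 layout): pctSubjects, pctMedian,
#'   pctQ25, pctQ75, absMedian, absQ25, absQ75, plus the per-subject
#'   percentages as attribute `"perSubjectPct"`.
#' @export
overlapStats <- function(subjectMasks, nucleusMask, voxelVolumeMm3 = NULL) {
  if (is(nucleusMask, "ScalarVolume")) nucleusMask <- nucleusMask@data
  nIdx <- which(nucleusMask > 0)
  if (!length(nIdx)) stop("nucleus mask is empty", call. = FALSE)
  if (is.null(voxelVolumeMm3))
    voxelVolumeMm3 <- prod(subjectMasks[[1]]@voxelSize)
  inter <- vapply(subjectMasks, function(m) sum(m@data[nIdx] > 0), numeric(1))
  pct <- 100 * inter / length(nIdx)
  absV <- inter * voxelVolumeMm3
  out <- data.frame(pctSubjects = 100 * mean(inter > 0),
                    pctMedian = stats::median(pct),
                    pctQ25 = pctl(pct, 0.25), pctQ75 = pctl(pct, 0.75),
                    absMedian = stats::median(absV),
                    absQ25 = pctl(absV, 0.25), absQ75 = pctl(absV, 0.75))
  attr(out, "perSubjectPct") <- pct
  out
}

#' Overlap table across an atlas
#'
#' Runs [overlapStats()] for every nucleus of an atlas [ROISet-class] and
#' binds the rows into the Table-3-style report.
#'
#' @param subjectMasks list of binary [ScalarVolume-class] in group space.
#' @param atlas a [ROISet-class]; probabilistic inputs should be binarised
#'   at `probThreshold` beforehand by the caller or via this argument.
#' @param probThreshold binarisation level applied to the atlas masks
#'   (default 0.5; irrelevant for already-binary masks).
#' @return data.frame with one row per nucleus.
#' @export
overlapTable <- function(subjectMasks, atlas, probThreshold = 0.5) {
  rows <- lapply(names(atlas@masks), function(nm) {
    cbind(nucleus = nm,
          overlapStats(subjectMasks, atlas@masks[[nm]] > probThreshold))
  })
  do.call(rbind, rows)
}

#' Dice coefficient between two binary masks
#'
#' 2|A n B| / (|A| + |B|); returns NA when both masks are empty.
#'
#' @param a,b binary [ScalarVolume-class] or 3D arrays.
#' @return Dice overlap in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "ScalarVolume")) a <- a@data
  if (is(b, "ScalarVolume")) b <- b@data
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
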