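#' Deterministic streamline tracking on a direction field
#'
#' Euler integration in both directions from every seed: at each point the
#' direction field is interpolated componentwise (trilinear), renormalised
#' and sign-aligned with the previous step (the field's axis convention is
#' sign-ambiguous).  A half-track stops when the next point leaves the
#' tracking mask, when the turn between consecutive steps exceeds
#' `angleDeg`, when the direction is degenerate, or when the total length
#' reaches `maxLenMm`.  The two halves are concatenated through the seed
#' and streamlines shorter than `minLenMm` are discarded.  Defaults are
#' the pipeline's tracking constants: step 0.85 mm, angle 35 degrees,
#' minimum length 20 mm, maximum length 250 mm.
#'
#' @param field a [DirectionField-class].
#' @param seeds N x 3 matrix of world-mm seed points, or a binary
#'   [ScalarVolume-class]/array whose nonzero voxel centres seed the tracks.
#' @param stepMm integration step (> 0).
#' @param angleDeg per-step angle threshold in degrees (0, 90).
#' @param minLenMm minimum retained streamline length.
#' @param maxLenMm maximum streamline length.
#' @return a [StreamlineSet-class]; the number of seeds skipped for lying
#'   outside the mask is attached as attribute `"nSkippedSeeds"`.
#' @export
trackStreamlines <- function(field, seeds, stepMm = 0.85, angleDeg = 35,
                             minLenMm = 20, maxLenMm = 250) {
  stopifnot(stepMm > 0, angleDeg > 0, angleDeg < 90)
  if (is(seeds, "ScalarVolume")) seeds <- seeds@data
  if (is.array(seeds) && length(dim(seeds)) == 3L) {
    idx <- which(seeds > 0)
    seeds <- worldFromVoxel(field@affine, arrayInd(idx, dim(seeds)) - 1)
    if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3)
  }
  if (!is.matrix(seeds) || ncol(seeds) != 3L)
    stop("seeds must be an N x 3 world-mm matrix or a mask", call. = FALSE)
  Ainv <- solve(field@affine)
  cosThr <- cos(angleDeg * pi / 180)
  comps <- lapply(1:3, function(k) field@vectors[, , , k])
  maskArr <- field@mask
  toVox <- function(p) drop(applyAffine(Ainv, p))
  inMask <- function(p) nearestSample(maskArr, matrix(toVox(p), 1)) > 0
  dirAt <- function(p) {
    v <- vapply(comps, function(cmp)
      trilinearSample(cmp, matrix(toVox(p), 1)), numeric(1))
    n <- sqrt(sum(v^2))
    if (n < 1e-6) return(NULL)
    v / n
  }
  totalBudget <- floor(maxLenMm / stepMm)   # steps per whole streamline
  halfTrack <- function(seed, dir0, maxSteps) {
    pts <- matrix(NA_real_, maxSteps + 1L, 3L)
    pts[1, ] <- seed
    p <- seed; prev <- dir0; n <- 1L
    while (n <= maxSteps) {
      pNext <- p + stepMm * prev
      if (!inMask(pNext)) break
      pts[n + 1L, ] <- pNext
      n <- n + 1L
      dNew <- dirAt(pNext)
      if (is.null(dNew)) break
      if (sum(dNew * prev) < 0) dNew <- -dNew  # sign-align with last step
      if (sum(dNew * prev) < cosThr) break     # angle threshold
      p <- pNext; prev <- dNew
    }
    pts[seq_len(n), , drop = FALSE]
  }
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(seeds))) {
    seed <- seeds[i, ]
    if (!inMask(seed)) { skipped <- skipped + 1L; next }
    d0 <- dirAt(seed)
    if (is.null(d0)) { skipped <- skipped + 1L; next }
    fwd <- halfTrack(seed, d0, totalBudget)
    bwd <- halfTrack(seed, -d0, totalBudget - (nrow(fwd) - 1L))
    line <- rbind(bwd[rev(seq_len(nrow(bwd)))[-nrow(bwd)], , drop = FALSE],
                  fwd)
    len <- (nrow(line) - 1L) * stepMm
    if (len >= minLenMm && len <= maxLenMm + stepMm)
      out[[length(out) + 1L]] <- line
  }
  res <- new("StreamlineSet", points = out, stepMm = stepMm)
  attr(res, "nSkippedSeeds") <- skipped
  res
}

setMethod("show", "StreamlineSet", function(object) {
  cat("StreamlineSet:", length(object@points), "streamlines")
  if (length(object@points))
    cat(", length", paste(signif(range(streamlineLengths(object)), 4),
                          collapse = " .. "), "mm")
  cat("\n")
})

#' Streamline lengths in mm
#'
#' @param streamlines a [StreamlineSet-class].
#' @return numeric vector of summed segment lengths.
#' @export
streamlineLengths <- function(streamlines) {
  vapply(streamlines@points, function(p) {
    if (nrow(p) < 2L) return(0)
    sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                        p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1))
}

# indices of the voxels containing each world point (0-based -> 1-based
# linear index into grid d); NA outside the grid
pointVoxelIndex <- function(pts, affineMat, d) {
  vox <- round(applyAffine(solve(affineMat), pts))
  if (is.null(dim(vox))) vox <- matrix(vox, ncol = 3)
  ok <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 & vox[, 2] >= 0 &
        vox[, 2] <= d[2] - 1 & vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  out <- rep(NA_integer_, nrow(vox))
  out[ok] <- as.integer(vox[ok, 1] + d[1] * vox[ok, 2] +
                          d[1] * d[2] * vox[ok, 3] + 1)
  out
}

#' Select streamlines by region crossing
#'
#' Keeps streamlines with at least one point whose containing voxel lies in
#' `roiA` and at least one in `roiB` — the rule that restricts a whole-brain
#' tractogram to the tracts linking two network regions.
#'
#' @param streamlines a [StreamlineSet-class].
#' @param roiA,roiB non-empty logical 3D arrays on `grid`.
#' @param grid a [VolumeGrid-class] object defining voxelisation.
#' @param mode only `"crosses_both"` is implemented.
#' @return the selected [StreamlineSet-class].
#' @export
selectStreamlines <- function(streamlines, roiA, roiB, grid,
                              mode = "crosses_both") {
  mode <- match.arg(mode, "crosses_both")
  if (!any(roiA > 0) || !any(roiB > 0))
    stop("empty ROI", call. = FALSE)
  d <- gridDim(grid)
  keep <- vapply(streamlines@points, function(p) {
    vi <- pointVoxelIndex(p, affine(grid), d)
    vi <- vi[!is.na(vi)]
    any(roiA[vi] > 0) && any(roiB[vi] > 0)
  }, logical(1))
  new("StreamlineSet", points = streamlines@points[keep],
      stepMm = streamlines@stepMm)
}

#' Endpoint connectome from a streamline set
#'
#' A streamline increments cell (i, j) exactly when its first point's voxel
#' lies in ROI i and its last point's voxel in ROI j (i != j); counts are
#' symmetrised.  Streamlines not ending in two distinct ROIs are ignored
#' (their number is attached as attribute `"nUnassigned"`).  If ROIs
#' overlap at an endpoint the first ROI in declared order wins, with a
#' warning.
#'
#' @param streamlines a [StreamlineSet-class].
#' @param rois a [ROISet-class] with >= 2 regions.
#' @return a [Connectome-class] (binarisation threshold 1).
#' @export
endpointsConnectome <- function(streamlines, rois) {
  n <- length(rois@masks)
  if (n < 2L) stop("need at least 2 ROIs", call. = FALSE)
  d <- gridDim(rois)
  roiOfVoxel <- array(0L, d)
  overlapWarned <- FALSE
  for (k in rev(seq_len(n))) {      # earlier ROIs overwrite later ones
    idx <- which(rois@masks[[k]])
    if (any(roiOfVoxel[idx] != 0L)) overlapWarned <- TRUE
    roiOfVoxel[idx] <- k
  }
  if (overlapWarned)
    warning("overlapping ROIs: endpoints assigned to the first ROI in ",
            "declared order", call. = FALSE)
  M <- matrix(0, n, n)
  unassigned <- 0L
  for (p in streamlines@points) {
    ends <- pointVoxelIndex(p[c(1L, nrow(p)), , drop = FALSE],
                            rois@affine, d)
    lab <- ifelse(is.na(ends), 0L, roiOfVoxel[ends])
    if (any(lab == 0L) || lab[1] == lab[2]) { unassigned <- unassigned + 1L }
    else M[lab[1], lab[2]] <- M[lab[1], lab[2]] + 1
  }
  M <- M + t(M)
  out <- new("Connectome", counts = M, roiNames = names(rois@masks),
             binariseThreshold = 1)
  attr(out, "nUnassigned") <- unassigned
  out
}

#' @rdname roi-accessors
#' @export
setMethod("counts", "Connectome", function(x) {
  dimnames(x@counts) <- list(x@roiNames, x@roiNames)
  x@counts
})

#' @rdname roi-accessors
#' @export
setMethod("adjacency", "Connectome", function(x) {
  A <- (x@counts >= x@binariseThreshold) + 0
  diag(A) <- 0
  dimnames(A) <- list(x@roiNames, x@roiNames)
  A
})

#' Binarise a connectome at a count threshold
#'
#' Edges are cells with at least `threshold` streamlines (default 1: any
#' streamline implies a connection, since counts do not measure connection
#' strength).  Returns the connectome with its threshold set; use
#' [adjacency()] to materialise the binary matrix.
#'
#' @param connectome a [Connectome-class] or a raw count matrix.
#' @param threshold count threshold >= 1.
#' @return a [Connectome-class].
#' @export
binarizeConnectome <- function(connectome, threshold = 1) {
  stopifnot(threshold >= 1)
  if (is.matrix(connectome))
    connectome <- new("Connectome", counts = connectome,
                      roiNames = rownames(connectome) %||%
                        sprintf("roi%02d", seq_len(nrow(connectome))),
                      binariseThreshold = 1)
  new("Connectome", counts = connectome@counts,
      roiNames = connectome@roiNames, binariseThreshold = threshold)
}

setMethod("show", "Connectome", function(object) {
  A <- adjacency(object)
  cat("Connectome:", length(object@roiNames), "regions,",
      sum(A[upper.tri(A)]), "edges at count threshold",
      object@binariseThreshold, "\n")
})

#' Binary tract visitation map
#'
#' Marks every voxel intersected by a streamline; segments are supersampled
#' at half the integration step so diagonal segments cannot skip voxels.
#'
#' @param streamlines a [StreamlineSet-class].
#' @param grid a [VolumeGrid-class] defining the output lattice.
#' @param supersample supersample segments at `stepMm / 2` (default TRUE).
#' @return a binary [ScalarVolume-class].
#' @export
tractDensityMap <- function(streamlines, grid, supersample = TRUE) {
  d <- gridDim(grid)
  arr <- array(0, d)
  for (p in streamlines@points) {
    if (supersample && nrow(p) > 1L) {
      mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2
      p <- rbind(p, mid)
    }
    vi <- pointVoxelIndex(p, affine(grid), d)
    arr[vi[!is.na(vi)]] <- 1
  }
  scalarVolume(arr, voxelSize = voxelSize(grid), affine = affine(grid))
}

# --- TCK (MRtrix track file) input/output ---------------------------------

#' Read and write streamlines in TCK format
#'
#' Minimal MRtrix .tck support: Float32LE triplets delimited by NaN
#' between tracks and Inf at the end of the file, with a plain-text
#' header.  Points are world-mm coordinates.
#'
#' @param streamlines a [StreamlineSet-class].
#' @param path file path.
#' @param stepMm step size recorded when reading (for the constructed
#'   object); defaults to the median point spacing.
#' @return `writeTck` returns the path invisibly; `readTck` a
#'   [StreamlineSet-class].
#' @name tck-io
NULL

#' @rdname tck-io
#' @export
writeTck <- function(streamlines, path) {
  hdr <- c("mrtrix tracks", "datatype: Float32LE",
           paste0("count: ", length(streamlines@points)),
           paste0("step_size: ", streamlines@stepMm))
  hdrNoOffset <- paste0(paste(hdr, collapse = "\n"), "\nfile: . ")
  # header length must include its own offset digits
  off <- nchar(hdrNoOffset, type = "bytes") + 10L
  repeat {
    full <- paste0(hdrNoOffset, off, "\nEND\n")
    realOff <- nchar(full, type = "bytes")
    if (realOff == off) break
    off <- realOff
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(full, con, eos = NULL)
  for (p in streamlines@points) {
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname tck-io
#' @export
readTck <- function(path, stepMm = NULL) {
  raw <- readBin(path, "raw", n = file.size(path))
  hdrEnd <- grepRaw("END\n", raw)[1]
  if (is.na(hdrEnd)) stop("not a TCK file: no END marker", call. = FALSE)
  hdr <- rawToChar(raw[seq_len(hdrEnd - 1L)])
  lines <- strsplit(hdr, "\n")[[1]]
  if (!startsWith(lines[1], "mrtrix tracks"))
    stop("not a TCK file", call. = FALSE)
  offLine <- grep("^file: \\.", lines, value = TRUE)
  off <- as.integer(sub("^file: \\. ", "", offLine))
  stepLine <- grep("^step_size:", lines, value = TRUE)
  if (is.null(stepMm))
    stepMm <- if (length(stepLine))
      as.numeric(sub("^step_size: *", "", stepLine[1])) else 1
  vals <- readBin(raw[(off + 1L):length(raw)], "numeric",
                  n = (length(raw) - off) / 4L, size = 4L,
                  endian = "little")
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  isInf <- is.infinite(pts[, 1])
  isNaN <- is.nan(pts[, 1])
  end <- which(isInf)[1]
  if (!is.na(end)) pts <- pts[seq_len(end - 1L), , drop = FALSE]
  breaks <- which(is.nan(pts[, 1]))
  startsAt <- c(1L, breaks + 1L)
  endsAt <- c(breaks - 1L, nrow(pts))
  keep <- startsAt <= endsAt
  tracks <- Map(function(s, e) pts[s:e, , drop = FALSE],
                startsAt[keep], endsAt[keep])
  new("StreamlineSet", points = unname(tracks), stepMm = stepMm)
}
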