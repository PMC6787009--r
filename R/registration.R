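#' Construct registration parameters
#'
#' @param pyramidLevels resolution levels (downsampling by 2 per level).
#' @param itersPerLevel iterations per level, coarsest first.
#' @param fluidSigma Gaussian sigma (voxels) smoothing each update field.
#' @param diffusionSigma Gaussian sigma (voxels) smoothing the total field.
#' @param maxStep per-iteration displacement cap (voxels).
#' @param nTemplateIters groupwise template iterations (default 4).
#' @return a [RegistrationParams-class].
#' @export
registrationParams <- function(pyramidLevels = 3L,
                               itersPerLevel = c(30L, 20L, 10L),
                               fluidSigma = 1.0, diffusionSigma = 1.0,
                               maxStep = 0.5, nTemplateIters = 4L) {
  new("RegistrationParams", pyramidLevels = as.integer(pyramidLevels),
      itersPerLevel = as.integer(itersPerLevel), fluidSigma = fluidSigma,
      diffusionSigma = diffusionSigma, maxStep = maxStep,
      nTemplateIters = as.integer(nTemplateIters))
}

# smooth-then-decimate by 2 (0-based voxels 0, 2, 4, ...)
downsample2 <- function(arr) {
  arr <- sepGaussSmooth(arr, rep(1, 3))
  d <- dim(arr)
  arr[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2), drop = FALSE]
}

# interpolate a coarse field onto a fine grid, doubling the vectors
upsampleField2 <- function(u, dFine) {
  pts <- gridCoords(dFine) / 2
  out <- array(0, c(dFine, 3L))
  for (k in 1:3)
    out[, , , k] <- array(2 * trilinearSample(u[, , , k], pts, mode = "clamp"),
                          dFine)
  out
}

ncc <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(as.vector(a), as.vector(b))
}

# one pyramid level of greedy demons-style iterations; returns the field
# (and, at the finest level, the best-NCC iterate)
demonsLevel <- function(movingArr, fixedArr, u, iters, params, keepBest) {
  d <- dim(fixedArr)
  coords <- gridCoords(d)
  gf <- gradient3(fixedArr)
  g1 <- as.vector(gf[, , , 1]); g2 <- as.vector(gf[, , , 2])
  g3 <- as.vector(gf[, , , 3])
  gg <- g1^2 + g2^2 + g3^2
  fluid <- rep(params@fluidSigma, 3)
  diffu <- rep(params@diffusionSigma, 3)
  best <- NULL; bestNcc <- -Inf
  for (it in seq_len(iters)) {
    pts <- coords + matrix(u, ncol = 3L)
    warped <- trilinearSample(movingArr, pts)
    if (keepBest) {
      v <- ncc(warped, fixedArr)
      if (!is.na(v) && v > bestNcc) { bestNcc <- v; best <- u }
    }
    diffI <- as.vector(fixedArr) - warped
    denom <- gg + diffI^2
    ok <- denom > 1e-12
    f1 <- f2 <- f3 <- numeric(length(denom))
    f1[ok] <- diffI[ok] * g1[ok] / denom[ok]
    f2[ok] <- diffI[ok] * g2[ok] / denom[ok]
    f3[ok] <- diffI[ok] * g3[ok] / denom[ok]
    nrm <- sqrt(f1^2 + f2^2 + f3^2)
    sc <- ifelse(nrm > params@maxStep, params@maxStep / nrm, 1)
    upd <- array(c(f1 * sc, f2 * sc, f3 * sc), c(d, 3L))
    if (params@fluidSigma > 0)
      for (k in 1:3) upd[, , , k] <- sepGaussSmooth(upd[, , , k], fluid)
    u <- u + upd
    if (params@diffusionSigma > 0)
      for (k in 1:3) u[, , , k] <- sepGaussSmooth(u[, , , k], diffu)
  }
  if (keepBest) {
    pts <- coords + matrix(u, ncol = 3L)
    v <- ncc(trilinearSample(movingArr, pts), fixedArr)
    if (!is.na(v) && v > bestNcc) { bestNcc <- v; best <- u }
    u <- best
  }
  u
}

#' Greedy multi-resolution nonlinear registration of two scalar maps
#'
#' Registers `moving` to `fixed` with a demons-style greedy scheme:
#' intensity-difference forces along the fixed-image gradient, per-iteration
#' updates capped at `maxStep` voxels and smoothed (fluid regularisation),
#' the accumulated field smoothed (diffusion regularisation), run over a
#' coarse-to-fine pyramid.  Normalized cross-correlation (NCC) with the
#' fixed image is tracked at the finest level and the best iterate kept, so
#' the returned field never degrades the initial NCC.  A constant input
#' image (NCC undefined) returns a zero field with a warning.
#'
#' @param moving,fixed [ScalarVolume-class] maps on one grid.
#' @param params a [RegistrationParams-class].
#' @return a [DisplacementField-class] (subject-to-fixed, pull convention)
#'   with attribute `"ncc"` = c(before, after).
#' @export
registerPair <- function(moving, fixed, params = registrationParams()) {
  stopIfDifferentGrid(moving, fixed, "moving and fixed maps")
  zero <- displacementField(0, reference = fixed)
  if (stats::sd(moving@data) == 0 || stats::sd(fixed@data) == 0) {
    warning("constant input image: NCC undefined, returning zero field",
            call. = FALSE)
    attr(zero, "ncc") <- c(NA_real_, NA_real_)
    return(zero)
  }
  nccBefore <- ncc(moving@data, fixed@data)
  L <- params@pyramidLevels
  movPyr <- fixPyr <- vector("list", L)
  movPyr[[1]] <- moving@data; fixPyr[[1]] <- fixed@data
  if (L > 1) for (l in 2:L) {
    movPyr[[l]] <- downsample2(movPyr[[l - 1]])
    fixPyr[[l]] <- downsample2(fixPyr[[l - 1]])
  }
  u <- array(0, c(dim(fixPyr[[L]]), 3L))
  for (l in L:1) {
    u <- demonsLevel(movPyr[[l]], fixPyr[[l]], u,
                     iters = params@itersPerLevel[L - l + 1L],
                     params = params, keepBest = (l == 1L))
    if (l > 1) u <- upsampleField2(u, dim(fixPyr[[l - 1]]))
  }
  field <- displacementField(u, reference = fixed)
  nccAfter <- ncc(resampleVolume(moving, field)@data, fixed@data)
  if (!is.na(nccAfter) && nccAfter < nccBefore) {
    field <- zero
    nccAfter <- nccBefore
  }
  attr(field, "ncc") <- c(before = nccBefore, after = nccAfter)
  field
}

#' Iterative groupwise functional template construction
#'
#' Builds a functional-space template from individual maps: the initial
#' template is the voxelwise median of the inputs; each of the
#' `nTemplateIters` iterations registers every map to the current template,
#' removes the common drift by subtracting the voxelwise mean field from
#' every subject's field (so the template does not wander), warps the maps
#' and recomputes the template.  Inverse warps are obtained with
#' [invertField()].
#'
#' @param maps list of at least two [ScalarVolume-class] on one grid;
#'   constant maps are excluded with a warning.
#' @param params a [RegistrationParams-class]; `nTemplateIters` controls
#'   the groupwise iterations (default 4).
#' @param templateStat `"median"` (default, robust to outlying subjects) or
#'   `"mean"` for the per-iteration template update.
#' @return a [TemplateResult-class].
#' @export
buildFunctionalTemplate <- function(maps, params = registrationParams(),
                                    templateStat = c("median", "mean")) {
  templateStat <- match.arg(templateStat)
  keep <- vapply(maps, function(m) stats::sd(m@data) > 0, logical(1))
  if (!all(keep))
    warning(sum(!keep), " constant map(s) excluded from template building",
            call. = FALSE)
  maps <- maps[keep]
  if (length(maps) < 2L)
    stop("need at least 2 usable (non-constant) maps", call. = FALSE)
  for (m in maps[-1]) stopIfDifferentGrid(maps[[1]], m, "maps")
  d <- gridDim(maps[[1]])
  combine <- function(lst) {
    X <- vapply(lst, function(m) as.vector(m@data), numeric(prod(d)))
    v <- if (templateStat == "median") rowMedians_(X) else rowMeans(X)
    scalarVolume(array(v, d), voxelSize = maps[[1]]@voxelSize,
                 affine = maps[[1]]@affine)
  }
  template <- combine(maps)
  fields <- NULL
  log <- data.frame(iteration = integer(), meanNCC = numeric())
  for (it in seq_len(params@nTemplateIters)) {
    fields <- lapply(maps, registerPair, fixed = template, params = params)
    meanU <- Reduce(`+`, lapply(fields, slot, "vectors")) / length(fields)
    fields <- lapply(fields, function(f)
      displacementField(f@vectors - meanU, reference = template))
    warped <- lapply(seq_along(maps), function(i)
      resampleVolume(maps[[i]], fields[[i]]))
    template <- combine(warped)
    mncc <- mean(vapply(warped, function(w) ncc(w@data, template@data),
                        numeric(1)), na.rm = TRUE)
    log <- rbind(log, data.frame(iteration = it, meanNCC = mncc))
  }
  inverses <- lapply(fields, invertField)
  new("TemplateResult", template = template, forwardWarps = fields,
      inverseWarps = inverses, convergence = log)
}

setMethod("show", "TemplateResult", function(object) {
  cat("TemplateResult:", length(object@forwardWarps), "subjects,",
      nrow(object@convergence), "template iterations; final mean NCC =",
      signif(utils::tail(object@convergence$meanNCC, 1), 4), "\n")
})

#' Map a functional-space volume back to the group (structural) grid
#'
#' Resamples a subject's functional-space map through that subject's
#' inverse warp, the route by which individual functional-space results are
#' compared against anatomy defined on the common grid.
#'
#' @param subjectMap a [ScalarVolume-class] on the template grid.
#' @param inverseWarp the subject's inverse [DisplacementField-class] from
#'   [buildFunctionalTemplate()].
#' @param interpolation `"trilinear"` for maps, `"nearest"` for masks.
#' @return a [ScalarVolume-class] on the group grid.
#' @export
toGroupSpace <- function(subjectMap, inverseWarp,
                         interpolation = c("trilinear", "nearest")) {
  if (missing(inverseWarp) || is.null(inverseWarp))
    stop("an inverse warp is required", call. = FALSE)
  resampleVolume(subjectMap, inverseWarp, match.arg(interpolation))
}
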