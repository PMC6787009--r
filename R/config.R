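#' Canonical analysis constants
#'
#' One place for the pipeline's named constants, so every stage agrees on
#' them: the connectivity threshold (r = 0.3, a medium effect size), the
#' number of groupwise template iterations (4), the tracking parameters
#' (step 0.85 mm, angle threshold 35 degrees, minimum length 20 mm, maximum
#' length 250 mm), the connectome binarisation count threshold (1), the
#' variance-smoothing sigma for tract-map t-tests (4 mm), and the
#' family-wise alpha (0.05) whose Bonferroni division across 528 unique
#' pairs of 33 regions gives the per-comparison level below 1e-4.
#'
#' @param ... named overrides of individual constants.
#' @return a named list of constants.
#' @examples
#' analysisConfig()$rThreshold
#' analysisConfig(nPermutations = 500)$nPermutations
#' @export
analysisConfig <- function(...) {
  cfg <- list(
    rThreshold = 0.3,
    nTemplateIters = 4L,
    familyAlpha = 0.05,
    stepMm = 0.85,
    angleDeg = 35,
    minLenMm = 20,
    maxLenMm = 250,
    binariseThreshold = 1,
    varianceSmoothMm = 4,
    nPermutations = 1000L,
    smoothFwhmFactor = 1.5  # spatial smoothing FWHM as multiple of voxel size
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(ov)] <- ov
  cfg
}
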