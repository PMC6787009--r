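#' Simulate a ground-truth cohort
#'
#' Generates the study conditions every downstream stage is scored against:
#' a shared network template of six large cortical-like blobs (support
#' radius 7 voxels, amplitude 0.9) and two small subcortical-like blobs
#' (support radius 3 voxels, amplitude 0.4) on a 32^3 grid of 2 mm voxels;
#' smooth subject-specific diffeomorphic warps (bulk quasi-translation plus
#' local deformation of smoothness sigma 6 voxels, rescaled to a maximum
#' displacement of 2 voxels) that misalign the subjects on the common
#' grid; a standardised AR(1) latent network signal shared by all
#' nodes; nuisance regressors (linear drift and a slow oscillation); 40
#' seed centres (20 per hemisphere) riding on the cortical blobs, mapped
#' into each subject's space through that subject's warp; a small synthetic
#' atlas with thalamus-like and tiny mammillary-body-like nuclei; and a
#' planted hub in the true structural adjacency.
#'
#' The subcortical blobs are deliberately small relative to the warps: a
#' 2-voxel displacement moves them by most of their width, so they vanish
#' from the pre-alignment group median but survive functional alignment —
#' the misalignment regime the pipeline exists to fix.
#'
#' @param nSubjects number of subjects (default 20).
#' @param gridSize lattice size per axis (default 32).
#' @param voxelMm voxel size in mm (default 2).
#' @param maxDispVox maximum warp displacement in voxels (default 2).
#' @param warpSigmaVox warp smoothness sigma in voxels (default 6).
#' @param T time points per run (default 200).
#' @param snr latent-signal SNR at template value 1 (default 1.5).
#' @param rho AR(1) coefficient of the latent signal (default 0.3).
#' @param seed integer master seed; all per-subject seeds derive from it.
#' @return a [CohortGroundTruth-class].
#' @seealso [subjectTimeseries()], [subjectTemplate()], [subjectSeedSet()]
#' @export
simulateCohort <- function(nSubjects = 20L, gridSize = 32L, voxelMm = 2,
                           maxDispVox = 2, warpSigmaVox = 6, T = 200L,
                           snr = 1.5, rho = 0.3, seed = 1L) {
  aff <- diag(4); diag(aff)[1:3] <- voxelMm
  aff[1:3, 4] <- -voxelMm * gridSize / 2
  grid <- scalarVolume(array(0, rep(gridSize, 3)),
                       voxelSize = rep(voxelMm, 3), affine = aff)
  s <- voxelMm * gridSize / 64  # node layout scales with the field of view
  nodes <- data.frame(
    name = c("mpfc_l", "mpfc_r", "pcc_l", "pcc_r", "ppc_l", "ppc_r",
             "thal_l", "thal_r"),
    kind = rep(c("cortical", "subcortical"), c(6, 2)),
    x = s * c(-12, 12, -9, 9, -18, 18, -6, 6),
    y = s * c(18, 18, -16, -16, -4, -4, -2, -2),
    z = s * c(4, 4, 8, 8, -8, -8, 0, 0),
    radiusVox = c(rep(7, 6), rep(3, 2)),
    amplitude = c(rep(0.9, 6), rep(0.4, 2)))
  blobs <- data.frame(x = nodes$x, y = nodes$y, z = nodes$z,
                      radiusMm = nodes$radiusVox * voxelMm,
                      amplitude = nodes$amplitude)
  template <- makeTemplate(grid, blobs)

  # Subject warps model inter-individual variability as a bulk
  # quasi-translation plus smooth local deformation, rescaled so the
  # maximum displacement equals maxDispVox.  A pure smoothed-noise field
  # rescaled by its maximum has typical displacements of only ~0.2-0.3 of
  # the maximum, which would leave small structures essentially aligned;
  # the bulk component reproduces the regime where a small structure is
  # displaced by most of its own width between subjects.
  d <- rep(gridSize, 3)
  warps <- lapply(seq_len(nSubjects), function(i) {
    bulk <- withSeed(seed + i, {
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      dir * stats::runif(1, 0.6, 1) * maxDispVox
    })
    loc <- sampleSubjectWarp(grid, 0.5 * maxDispVox, warpSigmaVox,
                             seed = seed + 500L + i)
    u <- loc@vectors + array(rep(bulk, each = prod(d)), c(d, 3L))
    u <- u * (maxDispVox / max(sqrt(rowSums(matrix(u, ncol = 3L)^2))))
    displacementField(u, reference = grid)
  })

  # 40 seed centres: 20 per hemisphere, jittered over the cortical blobs
  cort <- nodes[nodes$kind == "cortical", ]
  perBlob <- c(7, 7, 6)
  seedCtr <- withSeed(seed + 900L, {
    rows <- NULL
    for (h in c(-1, 1)) {
      hemi <- cort[sign(cort$x) == h, ]
      for (b in seq_len(nrow(hemi))) {
        r <- hemi$radiusVox[b] * voxelMm / 3  # stay in the blob core
        n <- perBlob[b]
        jit <- matrix(stats::runif(n * 3, -r, r), n)
        rows <- rbind(rows, cbind(hemi$x[b] + jit[, 1], hemi$y[b] + jit[, 2],
                                  hemi$z[b] + jit[, 3]))
      }
    }
    rows
  })
  # a seed at template position c appears in subject space near c - u(c)
  seedCentres <- lapply(warps, function(w) {
    vox <- voxelFromWorld(aff, seedCtr)
    u <- vapply(1:3, function(k) trilinearSample(w@vectors[, , , k], vox,
                                                 mode = "clamp"),
                numeric(nrow(vox)))
    seedCtr - u * voxelMm
  })

  tt <- seq_len(T)
  confounds <- rbind(drift = as.vector(scale(tt)),
                     slow  = as.vector(scale(sin(2 * pi * tt / 48))))

  atlas <- makeAtlas(grid, data.frame(
    name = c("thal_l", "thal_r", "mamm_l"),
    x = s * c(-6, 6, -2), y = s * c(-2, -2, -9), z = s * c(0, 0, -4),
    radiusMm = c(2.9 * voxelMm, 2.9 * voxelMm, 1.25 * voxelMm)))

  A <- matrix(0L, 8, 8, dimnames = list(nodes$name, nodes$name))
  A["thal_l", ] <- 1L; A[, "thal_l"] <- 1L       # planted hub
  A["mpfc_l", "pcc_l"] <- A["pcc_l", "mpfc_l"] <- 1L
  A["mpfc_r", "pcc_r"] <- A["pcc_r", "mpfc_r"] <- 1L
  diag(A) <- 0L

  new("CohortGroundTruth", template = template, nodeCentres = nodes,
      trueWarps = warps, seedCentres = seedCentres, snr = snr, rho = rho,
      T = as.integer(T), noiseSd = 1 / snr, confounds = confounds,
      atlas = atlas, trueAdjacency = A, seed = as.integer(seed))
}

setMethod("show", "CohortGroundTruth", function(object) {
  cat("CohortGroundTruth:", length(object@trueWarps), "subjects on a",
      paste(gridDim(object@template), collapse = " x "), "grid,",
      nrow(object@nodeCentres), "network nodes, T =", object@T,
      ", snr =", object@snr, "\n")
})

#' Per-subject views of a synthetic cohort
#'
#' `subjectTemplate()` warps the ideal template into subject `i`'s space
#' (this is the subject's true network map on the common structural grid);
#' `subjectTimeseries()` simulates that subject's BOLD-like run from it;
#' `subjectSeedSet()` returns the 40 seed masks (2-voxel-radius spheres at
#' the subject-space seed centres).
#'
#' @param cohort a [CohortGroundTruth-class].
#' @param i subject index.
#' @return see Description.
#' @export
subjectTemplate <- function(cohort, i)
  resampleVolume(cohort@template, cohort@trueWarps[[i]])

#' @rdname subjectTemplate
#' @export
subjectTimeseries <- function(cohort, i)
  simulateTimeseries(subjectTemplate(cohort, i), T = cohort@T,
                     snr = cohort@snr, confounds = cohort@confounds,
                     rho = cohort@rho, seed = cohort@seed + 1000L + i)

#' @rdname subjectTemplate
#' @export
subjectSeedSet <- function(cohort, i) {
  ctr <- cohort@seedCentres[[i]]
  spec <- data.frame(name = sprintf("seed%02d", seq_len(nrow(ctr))),
                     x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                     radiusMm = 2 * voxelSize(cohort@template)[1])
  # neighbouring seeds legitimately overlap on a blob core
  suppressWarnings(makeAtlas(cohort@template, spec))
}
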