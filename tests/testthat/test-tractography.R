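uniformFieldX <- function(d, voxelSize = c(1, 1, 1), mask = NULL) {
  v <- array(0, c(d, 3)); v[, , , 1] <- 1
  if (is.null(mask)) mask <- array(1, d)
  directionField(v, mask, voxelSize = voxelSize)
}

test_that("a uniform field yields an exact straight line", {
  d <- c(70, 9, 9)
  fld <- uniformFieldX(d)
  line <- trackStreamlines(fld, matrix(c(35, 4, 4), 1))
  expect_length(line@points, 1)
  p <- line@points[[1]]
  # half-tracks run while the next point stays inside the 70 mm mask
  nFwd <- floor((69.5 - 35) / 0.85); nBwd <- floor((35 + 0.5) / 0.85)
  expect_equal(nrow(p), nFwd + nBwd + 1)
  expect_equal(streamlineLengths(line), (nFwd + nBwd) * 0.85)
  expect_equal(length(unique(p[, 2])), 1)
  expect_equal(length(unique(p[, 3])), 1)
  expect_equal(sort(p[, 1]),
               seq(35 - nBwd * 0.85, by = 0.85, length.out = nrow(p)),
               tolerance = 1e-9)

  # seed outside the mask is skipped, with a count
  none <- trackStreamlines(fld, matrix(c(-5, 4, 4), 1))
  expect_length(none@points, 0)
  expect_equal(attr(none, "nSkippedSeeds"), 1L)
})

test_that("tight curvature trips the angle threshold immediately", {
  d <- c(40, 40, 5)
  ctr <- c(19.5, 19.5)
  v <- array(0, c(d, 3))
  for (i in 1:40) for (j in 1:40) {
    t <- c(-(j - 1 - ctr[2]), (i - 1 - ctr[1]))
    n <- sqrt(sum(t^2)); if (n < 1e-6) t <- c(1, 0) else t <- t / n
    v[i, j, , 1] <- t[1]; v[i, j, , 2] <- t[2]
  }
  fld <- directionField(v, array(1, d))
  # seed 1 mm from the axis: per-step turn 2*atan(0.85 / 2) ~ 46 deg > 35
  res <- trackStreamlines(fld, matrix(c(ctr[1] + 1, ctr[2], 2), 1))
  expect_length(res@points, 0)
  # seed far from the axis: turn 2*atan(0.85 / 30) ~ 3 deg, tracks a circle
  res2 <- trackStreamlines(fld, matrix(c(ctr[1] + 15, ctr[2], 2), 1))
  expect_length(res2@points, 1)
})

test_that("a thin slab cannot host a 20 mm streamline", {
  d <- c(10, 30, 30)   # 10 mm thick along the tracking direction
  fld <- uniformFieldX(d)
  res <- trackStreamlines(fld, matrix(c(5, 15, 15), 1))
  expect_length(res@points, 0)
})

test_that("streamline selection keeps exactly the both-ROI crossers", {
  d <- c(30, 10, 10)
  grid <- scalarVolume(array(0, d))
  roiA <- array(FALSE, d); roiA[2:4, , ] <- TRUE
  roiB <- array(FALSE, d); roiB[26:28, , ] <- TRUE
  lineAt <- function(y, x0, x1) cbind(seq(x0, x1, by = 0.5), y, 5)
  sl <- new("StreamlineSet",
            points = c(lapply(1:4, function(y) lineAt(y, 1, 28)),   # both
                       lapply(5:8, function(y) lineAt(y, 1, 10)),   # A only
                       lapply(1:2, function(y) lineAt(y, 12, 20))), # neither
            stepMm = 0.5)
  kept <- selectStreamlines(sl, roiA, roiB, grid)
  expect_length(kept@points, 4)
  expect_error(selectStreamlines(sl, roiA & FALSE, roiB, grid), "empty")
})

test_that("endpoint connectomes tally first/last voxels only", {
  d <- c(30, 10, 10)
  masks <- list(A = array(FALSE, d), B = array(FALSE, d),
                C = array(FALSE, d))
  masks$A[1:3, , ] <- TRUE; masks$B[27:30, , ] <- TRUE
  masks$C[14:16, , ] <- TRUE
  rois <- roiSet(masks)
  mkLine <- function(x0, x1, y = 5) cbind(seq(x0, x1, by = 1), y, 5)
  sl <- new("StreamlineSet", points = c(
    lapply(1:5, function(i) mkLine(1, 28, y = i)),   # A -> B
    list(mkLine(15, 28)),                            # C -> B
    list(mkLine(5, 20)),                             # A -> nothing
    list(mkLine(10, 20))),                           # nothing
    stepMm = 1)
  cn <- endpointsConnectome(sl, rois)
  M <- counts(cn)
  expect_equal(M["A", "B"], 5)
  expect_equal(M["B", "A"], 5)
  expect_equal(M["C", "B"], 1)
  expect_equal(M["A", "C"], 0)
  expect_equal(attr(cn, "nUnassigned"), 2L)
  expect_equal(diag(M), c(A = 0, B = 0, C = 0))
})

test_that("connectome binarisation applies the count threshold", {
  M <- matrix(0, 3, 3); M[1, 2] <- M[2, 1] <- 1; M[1, 3] <- M[3, 1] <- 4
  cn <- binarizeConnectome(M, 1)
  expect_equal(adjacency(cn)[1, 2], 1)  # a single streamline is an edge
  expect_equal(adjacency(cn)[2, 3], 0)  # zero counts never are
  cn5 <- binarizeConnectome(M, 5)
  expect_equal(adjacency(cn5)[1, 3], 0) # 4 < 5
  expect_error(binarizeConnectome(M, 0), "threshold")
})

test_that("tract maps mark exactly the visited voxels", {
  d <- c(20, 8, 8)
  grid <- scalarVolume(array(0, d))
  expect_equal(max(volData(tractDensityMap(new("StreamlineSet",
                                               points = list(), stepMm = 1),
                                           grid))), 0)
  axis <- new("StreamlineSet", points = list(cbind(seq(2, 17, 1), 4, 4)),
              stepMm = 1)
  m <- tractDensityMap(axis, grid)
  expect_equal(sum(volData(m)), 16)
  expect_equal(which(volData(m)[, 5, 5] > 0), 3:18)

  diagSl <- new("StreamlineSet",
                points = list(cbind(seq(1, 15, 1.4), seq(1, 6, 0.5), 4)),
                stepMm = 1.4)
  sup <- volData(tractDensityMap(diagSl, grid, supersample = TRUE))
  raw <- volData(tractDensityMap(diagSl, grid, supersample = FALSE))
  expect_true(all(sup[raw > 0] > 0))      # supersampled map is a superset
  expect_gte(sum(sup), sum(raw))
})

test_that("TCK files round-trip streamlines", {
  set.seed(71)
  sl <- new("StreamlineSet",
            points = lapply(1:3, function(i)
              matrix(rnorm(3 * (3 + i)), ncol = 3)),
            stepMm = 0.85)
  f <- withr::local_tempfile(fileext = ".tck")
  writeTck(sl, f)
  back <- readTck(f)
  expect_length(back@points, 3)
  expect_equal(back@stepMm, 0.85)
  for (i in 1:3)
    expect_equal(back@points[[i]], sl@points[[i]], tolerance = 1e-6)
})

test_that("graph metrics reproduce closed-form cases", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  gK <- graphMetrics(list(K4))
  expect_equal(gK$groupMedian$degree, rep(3, 4))
  expect_equal(gK$groupMedian$betweenness, rep(0, 4))

  star <- matrix(0, 6, 6); star[1, 2:6] <- 1; star[2:6, 1] <- 1
  gS <- graphMetrics(list(star))
  expect_equal(gS$groupMedian$betweenness, c(1, rep(0, 5)))
  expect_equal(gS$groupMedian$degree, c(5, rep(1, 5)))

  path5 <- matrix(0, 5, 5)
  for (i in 1:4) path5[i, i + 1] <- path5[i + 1, i] <- 1
  gP <- graphMetrics(list(path5))
  expect_equal(gP$perSubject[[1]]$betweennessRaw[3], 4)
  expect_equal(gP$groupMedian$betweenness[3], 4 / 6, tolerance = 1e-12)

  expect_error(graphMetrics(list(matrix(c(0, 1, 0, 0), 2))), "symmetric")
})

test_that("graph metrics agree exactly with exhaustive path enumeration", {
  set.seed(72)
  for (rep in 1:50) {
    n <- sample(3:7, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, runif(1, 0.2, 0.9))
    A <- A + t(A)
    g <- graphMetrics(list(A))
    expect_equal(g$groupMedian$degree, rowSums(A))
    expect_equal(g$perSubject[[1]]$betweennessRaw, enumBetweenness(A),
                 tolerance = 1e-12)
  }
})

test_that("sum of degrees is twice the edge count; betweenness in [0, 1]", {
  set.seed(73)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.5)
    A <- A + t(A)
    g <- graphMetrics(list(A))
    expect_equal(sum(g$groupMedian$degree), 2 * sum(A) / 2)
    expect_true(all(g$groupMedian$betweenness >= 0 &
                      g$groupMedian$betweenness <= 1))
  }
})

test_that("planted-hub connectomes are recovered through the full chain", {
  co <- suppressWarnings(simulateCohort(nSubjects = 4L, gridSize = 16L,
                                        T = 40L, seed = 9L))
  sims <- simulateConnectome(co@trueAdjacency, 50, 20, seed = 10L)
  adjs <- lapply(sims, function(M) adjacency(binarizeConnectome(M, 1)))
  # binarised median network equals the truth
  medA <- (Reduce(`+`, adjs) / length(adjs)) >= 0.5
  expect_equal(medA + 0, co@trueAdjacency + 0, ignore_attr = TRUE)
  gm <- graphMetrics(adjs)
  hub <- which(co@nodeCentres$name == "thal_l")
  expect_equal(which.max(gm$groupMedian$betweenness), hub)
})
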