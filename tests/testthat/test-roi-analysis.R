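test_that("ROI extraction labels components and splits at the midline", {
  d <- c(20, 20, 10)
  aff <- diag(4); aff[1, 4] <- -10  # world x = voxel x - 10
  arr <- array(0, d)
  arr[3:5, 3:5, 3:5] <- 0.6          # wholly left of x = 0
  arr[14:17, 14:17, 5:8] <- 0.5      # wholly right
  gm <- scalarVolume(arr, affine = aff)
  rois <- extractRois(gm, 0.3)
  expect_length(rois@masks, 2)
  expect_setequal(vapply(rois@masks, sum, numeric(1)), c(27, 64))

  summ <- roiSummary(rois)
  blk <- summ[summ$voxels == 64, ]
  expect_equal(c(blk$x, blk$y, blk$z), c(4.5, 14.5, 5.5),
               tolerance = 1e-9)

  # one blob straddling the x = 0 plane splits into left/right parts
  arr2 <- array(0, d); arr2[9:13, 9:11, 4:6] <- 0.7  # world x -1..2
  rois2 <- extractRois(scalarVolume(arr2, affine = aff), 0.3)
  expect_length(rois2@masks, 2)
  expect_setequal(vapply(rois2@masks, sum, numeric(1)), c(2 * 9, 3 * 9))

  # strictly-greater-than rule
  arr3 <- array(0, d); arr3[5, 5, 5] <- 0.3
  expect_error(extractRois(scalarVolume(arr3, affine = aff), 0.3), "threshold")

  # manual masks are appended with user-supplied provenance
  manual <- list(thal = array(c(rep(FALSE, 10), TRUE,
                                rep(FALSE, prod(d) - 11)), d))
  rois3 <- suppressWarnings(extractRois(gm, 0.3, manualMasks = manual))
  expect_true("thal" %in% roiNames(rois3))
  expect_equal(rois3@provenance, "user-supplied")
})

test_that("ROI mean series average exactly over the mask", {
  set.seed(51)
  d <- c(4, 4, 2); T <- 30
  Y <- matrix(rnorm(prod(d) * T), prod(d))
  Y[2, ] <- -Y[1, ]
  ts <- timeSeriesVolume(array(Y, c(d, T)))
  single <- array(FALSE, d); single[3, 1, 1] <- TRUE
  pair <- array(FALSE, d); pair[1:2, 1, 1] <- TRUE
  rois <- suppressWarnings(roiSet(list(one = single, anti = pair)))
  mts <- roiMeanTimeseries(ts, rois)
  expect_equal(mts[, "one"], Y[3, ])
  expect_equal(max(abs(mts[, "anti"])), 0)

  # averaging suppresses independent noise around a shared signal
  s <- rnorm(200)
  Y2 <- matrix(rep(s, each = 10), 10) + matrix(rnorm(2000), 10)
  ts2 <- timeSeriesVolume(array(Y2, c(10, 1, 1, 200)))
  all10 <- suppressWarnings(roiSet(list(a = array(TRUE, c(10, 1, 1)))))
  expect_gt(cor(roiMeanTimeseries(ts2, all10)[, "a"], s), 0.95)
})

test_that("full correlation matrices behave like Pearson r", {
  set.seed(52)
  T <- 2000
  X <- matrix(rnorm(T * 6), T, 6,
              dimnames = list(NULL, paste0("r", 1:6)))
  cm <- correlationMatrix(X)
  expect_s4_class(cm, "CorrelationMatrix")
  off <- cm@values[upper.tri(cm@values)]
  expect_lt(max(abs(off)), 0.08)

  dup <- cbind(X[, 1, drop = FALSE], b = X[, 1])
  expect_equal(correlationMatrix(dup)@values[1, 2], 1)

  y <- 0.6 * scale(X[, 1]) + sqrt(1 - 0.36) * scale(X[, 2])
  cxy <- correlationMatrix(cbind(a = X[, 1], b = as.vector(y)))
  expect_equal(cxy@values[1, 2], 0.6, tolerance = 0.05)

  Z <- X; Z[, 3] <- 5
  expect_error(correlationMatrix(Z), "r3")
})

test_that("partial correlations invert the precision structure", {
  P <- matrix(c(1, 0.5, 0, 0.5, 1, 0.5, 0, 0.5, 1), 3)
  Sigma <- solve(P)
  R <- stats::cov2cor(Sigma)
  cm <- new("CorrelationMatrix", values = R, roiNames = c("a", "b", "c"),
            kind = "full")
  pc <- partialCorrelationMatrix(cm)
  expect_equal(pc@values[1, 2], -0.5, tolerance = 1e-10)
  expect_equal(pc@values[1, 3], 0, tolerance = 1e-10)
  expect_equal(diag(pc@values), rep(1, 3))

  # with two regions, partial equals full correlation
  set.seed(53)
  X <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(partialCorrelationMatrix(X)@values[1, 2],
               correlationMatrix(X)@values[1, 2], tolerance = 1e-10)

  # independent blocks: cross-block partials vanish at T = 2000
  X1 <- matrix(rnorm(2000 * 2), 2000); X1 <- cbind(X1, X1[, 1] + rnorm(2000))
  X2 <- matrix(rnorm(2000 * 2), 2000); X2 <- cbind(X2, X2[, 2] + rnorm(2000))
  XX <- cbind(X1, X2)
  colnames(XX) <- paste0("r", 1:6)
  pc2 <- partialCorrelationMatrix(XX)
  expect_lt(max(abs(pc2@values[1:3, 4:6])), 0.1)
})

test_that("a singular correlation matrix is rescued by the logged ridge", {
  set.seed(54)
  X <- matrix(rnorm(300), 100, 3)
  X <- cbind(X, X[, 1])  # exactly collinear pair
  colnames(X) <- paste0("r", 1:4)
  pc <- partialCorrelationMatrix(X)
  expect_gt(attr(pc, "ridge"), 0)
  expect_true(all(abs(pc@values) <= 1))
})

test_that("cellwise matrix tests apply the Bonferroni family rule", {
  expect_equal(bonferroniThreshold(33, 0.05), 0.05 / 528)
  expect_lt(bonferroniThreshold(33, 0.05), 1e-4)

  set.seed(55)
  nRoi <- 5; S <- 20
  mkMat <- function(z) {
    r <- tanh(z)
    M <- diag(nRoi)
    M[upper.tri(M)] <- r
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    new("CorrelationMatrix", values = M, roiNames = paste0("n", 1:nRoi),
        kind = "full")
  }
  m <- nRoi * (nRoi - 1) / 2
  zBase <- lapply(1:S, function(i) rnorm(m, 0.2, 0.1))
  matsA <- lapply(zBase, mkMat)
  # identical inputs: nothing is significant in the paired test
  same <- matrixTests(matsA, matsA)
  expect_equal(sum(same$paired$significant), 0)
  expect_equal(same$fractionSignificantPaired, 0)

  # a +0.3 z-shift in every cell (within-cell sd 0.1, 20 subjects): power ~ 1
  matsB <- lapply(1:S, function(i) mkMat(rnorm(m, 0.5, 0.1)))
  shift <- matrixTests(matsB, matsA)
  expect_equal(mean(shift$paired$significant), 1)
  expect_equal(shift$threshold, 0.05 / m)
  # the shifted condition is also one-sample significant against zero
  expect_gt(mean(shift$oneSampleA$significant), 0.9)
})
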