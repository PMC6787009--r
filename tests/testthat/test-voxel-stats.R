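volFrom <- function(v, d) scalarVolume(array(v, d))

test_that("group-map subtraction is exact and antisymmetric", {
  d <- c(6, 6, 6)
  a <- volFrom(rnorm(prod(d)), d)
  b <- volFrom(volData(a) + 0.5, d)
  expect_equal(max(abs(volData(subtractGroupMaps(a, a)))), 0)
  expect_equal(volData(subtractGroupMaps(b, a)), array(0.5, d))
  expect_equal(volData(subtractGroupMaps(a, b)),
               -volData(subtractGroupMaps(b, a)))
  expect_error(subtractGroupMaps(a, volFrom(0, c(5, 5, 5))), "grid")
})

test_that("paired t-maps match hand-computed statistics", {
  d <- c(2, 2, 1)
  mk <- function(vals) lapply(vals, function(v) volFrom(rep(v, 4), d))
  # voxelwise differences d = (1,2,3,4,5): t = 3 / (1.5811 / sqrt(5))
  A <- mk(c(1, 2, 3, 4, 5)); B <- mk(rep(0, 5))
  tm <- pairedTMap(pairedSample(A, B))
  expect_equal(volData(tm)[1, 1, 1], 4.242640687, tolerance = 1e-8)

  # alternating differences with mean zero
  Aalt <- mk(c(1, -1, 1, -1)); Balt <- mk(rep(0, 4))
  expect_equal(max(abs(volData(pairedTMap(pairedSample(Aalt, Balt))))), 0)

  # constant nonzero differences: zero variance, excluded
  Aconst <- mk(rep(1, 4)); Bconst <- mk(rep(0, 4))
  tm3 <- pairedTMap(pairedSample(Aconst, Bconst))
  expect_equal(max(abs(volData(tm3))), 0)
  expect_equal(attr(tm3, "nZeroVariance"), 4L)

  expect_error(pairedSample(mk(1:2), mk(c(0, 0))), "3 pairs")
})

test_that("sign-flip FWE p-values match the exhaustive oracle", {
  d <- c(1, 1, 1)
  diffs <- c(1, 2, 3, 4, 5, 6, 7, 8)
  A <- lapply(diffs, function(v) volFrom(v, d))
  B <- lapply(diffs, function(v) volFrom(0, d))
  smp <- pairedSample(A, B)

  pEx <- volData(permutationFwe(smp, nPerm = 10000L, seed = 1,
                                method = "exhaustive")$p)[1, 1, 1]
  expect_equal(pEx, bruteSignFlipP(diffs), tolerance = 1e-12)

  pSam <- volData(permutationFwe(smp, nPerm = 10000L, seed = 1,
                                 method = "sampled")$p)[1, 1, 1]
  expect_lt(abs(pSam - pEx), 0.02)

  # all-zero differences: corrected p = 1 everywhere
  Z <- lapply(1:6, function(i) volFrom(0, c(3, 1, 1)))
  expect_equal(min(volData(permutationFwe(pairedSample(Z, Z),
                                          nPerm = 200)$p)), 1)

  expect_warning(permutationFwe(smp, nPerm = 50), "coarse")
})

test_that("corrected p is monotone in |t| with the right floor", {
  set.seed(41)
  d <- c(10, 10, 5)
  n <- 12
  A <- lapply(1:n, function(i) volFrom(rnorm(prod(d)), d))
  B <- lapply(1:n, function(i) volFrom(rnorm(prod(d)), d))
  res <- permutationFwe(pairedSample(A, B), nPerm = 500L, seed = 2)
  tv <- abs(as.vector(volData(res$t)))
  pv <- as.vector(volData(res$p))
  ord <- order(tv)
  expect_true(all(diff(pv[ord]) <= 1e-12))
  expect_gte(min(pv), 1 / 501)
})

test_that("cluster tables report counts, peaks and centres of gravity", {
  set.seed(42)
  d <- c(12, 12, 6)
  n <- 8
  # plant two disjoint effect blocks on a null background
  eff <- array(0, d); eff[2:4, 2:4, 2:4] <- 2; eff[9:11, 8:10, 4:6] <- 2
  A <- lapply(1:n, function(i) volFrom(rnorm(prod(d), sd = 0.1) +
                                         as.vector(eff), d))
  B <- lapply(1:n, function(i) volFrom(rnorm(prod(d), sd = 0.1), d))
  smp <- pairedSample(A, B)
  res <- permutationFwe(smp, nPerm = 300L, seed = 3)
  tab <- clusterTable(res$p, res$t, smp, alpha = 0.05)
  expect_equal(nrow(tab), 2)
  expect_equal(sort(tab$voxels), c(27, 27))
  expect_true(all(tab$pMin < 0.05))
  expect_true(all(tab$effectSize > 1))
  # centres of gravity inside the planted blocks (0-based world = voxel here)
  expect_true(any(abs(tab$x - 3) < 1.5 & abs(tab$y - 3) < 1.5))
  expect_true(any(abs(tab$x - 10) < 1.5 & abs(tab$y - 9) < 1.5))

  # single suprathreshold voxel: cog equals its world coordinate
  p1 <- volFrom(1, d); t1 <- volFrom(0, d)
  pa <- volData(p1); pa[5, 6, 2] <- 0.01
  ta <- volData(t1); ta[5, 6, 2] <- 6
  tab1 <- clusterTable(volFrom(pa, d), volFrom(ta, d), smp, 0.05)
  expect_equal(c(tab1$x, tab1$y, tab1$z), c(4, 5, 1))

  # nothing suprathreshold: empty table, not an error
  expect_equal(nrow(clusterTable(p1, t1, smp, 0.05)), 0)
})

test_that("variance smoothing reduces to the plain t at sigma 0", {
  set.seed(43)
  d <- c(6, 6, 3)
  maps <- lapply(1:7, function(i) volFrom(rnorm(prod(d)), d))
  res0 <- oneSampleTMapVarSmooth(maps, smoothSigmaMm = 0, nPerm = 200L,
                                 seed = 4)
  D <- t(vapply(maps, function(m) as.vector(volData(m)), numeric(prod(d))))
  tRef <- apply(D, 2, function(x) mean(x) / (sd(x) / sqrt(length(x))))
  expect_equal(as.vector(volData(res0$t)), tRef, tolerance = 1e-10)

  # identical constant maps: identical t everywhere, no inference
  cm <- rep(list(volFrom(0.7, d)), 6)
  expect_warning(resC <- oneSampleTMapVarSmooth(cm, 4, nPerm = 100L),
                 "zero variance")
  expect_equal(length(unique(as.vector(volData(resC$t)))), 1L)
})

test_that("variance smoothing rescues a shared binary tract core", {
  set.seed(44)
  d <- c(10, 10, 4)
  core <- array(FALSE, d); core[5:6, 3:8, 2] <- TRUE
  n <- 10
  maps <- lapply(1:n, function(i) {
    m <- array(rbinom(prod(d), 1, 0.25), d)  # subject-specific stray voxels
    m[core] <- 1                             # every subject shares the core
    volFrom(m, d)
  })
  res <- oneSampleTMapVarSmooth(maps, smoothSigmaMm = 2, nPerm = 500L,
                                seed = 5)
  expect_lt(max(volData(res$p)[core]), 0.05)
  expect_gt(stats::quantile(volData(res$p)[!core], 0.5), 0.05)
})
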