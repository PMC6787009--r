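test_that("template blobs hit their stated centres and stay local", {
  grid <- scalarVolume(array(0, c(25, 25, 25)))
  one <- makeTemplate(grid, data.frame(x = 12, y = 12, z = 12, radiusMm = 6,
                                       amplitude = 1))
  expect_equal(max(volData(one)), 1)
  expect_equal(volData(one)[13, 13, 13], 1)  # voxel (12,12,12), 0-based

  empty <- makeTemplate(grid, data.frame(x = numeric(), y = numeric(),
                                         z = numeric(), radiusMm = numeric(),
                                         amplitude = numeric()))
  expect_equal(max(abs(volData(empty))), 0)

  # two radius-2mm blobs 20mm apart: >= 95% of each blob's mass within 6mm
  two <- makeTemplate(grid, data.frame(x = c(2, 22), y = 12, z = 12,
                                       radiusMm = 2, amplitude = 0.5))
  xyz <- as.matrix(expand.grid(0:24, 0:24, 0:24))
  d1 <- sqrt(rowSums(sweep(xyz, 2, c(2, 12, 12))^2))
  massNear <- sum(volData(two)[d1 <= 6])
  expect_gte(massNear / (sum(volData(two)) / 2), 0.95)

  expect_error(makeTemplate(grid, data.frame(x = 60, y = 12, z = 12,
                                             radiusMm = 2, amplitude = 1)),
               "outside")
  expect_error(makeTemplate(grid, data.frame(x = 12, y = 12, z = 12,
                                             radiusMm = 2, amplitude = 1.2)),
               "amplitude")
})

test_that("subject warps are reproducible, bounded and diffeomorphic", {
  grid <- scalarVolume(array(0, c(32, 32, 32)))
  expect_equal(max(abs(volData(sampleSubjectWarp(grid, 0, 6, seed = 1)))), 0)
  a <- sampleSubjectWarp(grid, 2, 6, seed = 9)
  b <- sampleSubjectWarp(grid, 2, 6, seed = 9)
  expect_identical(volData(a), volData(b))
  expect_equal(max(sqrt(rowSums(matrix(volData(a), ncol = 3)^2))), 2)
  expect_error(sampleSubjectWarp(grid, 3, 6, seed = 1), "invertibility")

  jac <- vapply(1:20, function(s)
    minJacobianDet(sampleSubjectWarp(grid, 2, 6, seed = s)), numeric(1))
  expect_gt(min(jac), 0)
})

test_that("simulated series carry the latent signal at the stated snr", {
  grid <- scalarVolume(array(0, c(10, 10, 10)))
  T <- 120
  # zero template: correlations with the latent signal are pure noise
  ts0 <- simulateTimeseries(grid, T = T, snr = 1.5, seed = 2)
  s <- attr(ts0, "latentSignal")
  Y <- matrix(volData(ts0), 1000, T)
  r0 <- abs(cor(t(Y), s))
  expect_lt(mean(r0), 3 / sqrt(T))

  # near-noiseless limit: template-1 voxel tracks the signal
  tpl <- scalarVolume(array(1, c(4, 4, 4)))
  ts1 <- simulateTimeseries(tpl, T = 60, snr = 1e6, seed = 3)
  expect_gt(cor(volData(ts1)[1, 1, 1, ], attr(ts1, "latentSignal")), 0.999)

  # determinism
  tsA <- simulateTimeseries(tpl, T = 60, snr = 1.5, seed = 4)
  tsB <- simulateTimeseries(tpl, T = 60, snr = 1.5, seed = 4)
  expect_identical(volData(tsA), volData(tsB))
  expect_error(simulateTimeseries(tpl, T = 60, snr = 0, seed = 1), "snr")
})

test_that("connectome simulation respects the generating adjacency", {
  A <- matrix(0, 5, 5); A[1, 2:5] <- 1; A[2:5, 1] <- 1  # star
  zero <- simulateConnectome(A * 0, meanCount = 50, nSubjects = 3, seed = 1)
  expect_true(all(vapply(zero, max, numeric(1)) == 0))

  s1 <- simulateConnectome(A, 50, 20, seed = 7)
  s2 <- simulateConnectome(A, 50, 20, seed = 7)
  expect_identical(s1, s2)
  # binarisation at threshold 1 recovers the truth in every subject
  rec <- vapply(s1, function(M) identical((M >= 1) + 0, A + 0), logical(1))
  expect_true(all(rec))
  expect_true(all(vapply(s1, function(M) isTRUE(all.equal(M, t(M))),
                         logical(1))))

  asym <- A; asym[1, 2] <- 2
  expect_error(simulateConnectome(asym, 50, 2, seed = 1), "symmetric")
})

test_that("synthetic atlas spheres have the right size and layout", {
  grid <- scalarVolume(array(0, c(20, 20, 20)))
  tiny <- makeAtlas(grid, data.frame(name = "pt", x = 10, y = 10, z = 10,
                                     radiusMm = 0.3))
  expect_equal(sum(tiny@masks$pt), 1)

  sph <- makeAtlas(grid, data.frame(name = "s", x = 10, y = 10, z = 10,
                                    radiusMm = 5))
  expect_gte(sum(sph@masks$s), 471)
  expect_lte(sum(sph@masks$s), 576)

  two <- makeAtlas(grid, data.frame(name = c("a", "b"), x = c(4, 15),
                                    y = 10, z = 10, radiusMm = 2))
  expect_equal(sum(two@masks$a & two@masks$b), 0)
  expect_error(makeAtlas(grid, data.frame(name = c("a", "a"), x = c(4, 15),
                                          y = 10, z = 10, radiusMm = 2)),
               "duplicate")
})

test_that("cohort generation is a pure function of its seed", {
  # on a 16^3 toy grid the scaled-down atlas nuclei legitimately overlap
  c1 <- suppressWarnings(simulateCohort(nSubjects = 3L, gridSize = 16L,
                                        T = 40L, seed = 5L))
  c2 <- suppressWarnings(simulateCohort(nSubjects = 3L, gridSize = 16L,
                                        T = 40L, seed = 5L))
  expect_identical(volData(c1@template), volData(c2@template))
  expect_identical(volData(c1@trueWarps[[2]]), volData(c2@trueWarps[[2]]))
  expect_identical(volData(subjectTimeseries(c1, 1)),
                   volData(subjectTimeseries(c2, 1)))
  expect_true(all(volData(c1@template) >= 0 & volData(c1@template) <= 1))
  expect_gt(min(vapply(c1@trueWarps, minJacobianDet, numeric(1))), 0)
})
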