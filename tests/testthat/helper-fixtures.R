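# Shared fixtures and independent oracles, built in code at test time.

# smooth multi-blob image used for registration / resampling checks
blobImage <- function(d = c(24, 24, 24), centres = rbind(c(8, 12, 10),
                                                         c(16, 10, 14)),
                      sigma = 3, amp = 0.9, voxelSize = c(1, 1, 1)) {
  xyz <- as.matrix(expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                               z = seq_len(d[3]) - 1))
  val <- rep(0, nrow(xyz))
  for (i in seq_len(nrow(centres)))
    val <- val + amp * exp(-rowSums(sweep(xyz, 2, centres[i, ])^2) /
                             (2 * sigma^2))
  scalarVolume(array(pmin(val, 1), d), voxelSize = voxelSize)
}

# random invertible affine: rotation-ish linear part plus translation
randomAffine <- function() {
  M <- matrix(rnorm(9), 3)
  M <- qr.Q(qr(M)) %*% diag(runif(3, 0.5, 3))
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- runif(3, -20, 20)
  A
}

# smooth displacement field that vanishes near the grid boundary
taperedField <- function(d, maxDisp = 1, seed = 1) {
  ref <- scalarVolume(array(0, d))
  f <- sampleSubjectWarp(ref, maxDisp, max(3, maxDisp / 0.4), seed = seed)
  w <- function(n) pmin(1, pmin(seq_len(n) - 1, n - seq_len(n)) / 3)
  taper <- outer(outer(w(d[1]), w(d[2])), w(d[3]))
  u <- volData(f)
  for (k in 1:3) u[, , , k] <- u[, , , k] * taper
  displacementField(u, reference = ref)
}

# Exhaustive betweenness oracle: enumerates every simple path between every
# node pair, keeps the shortest ones, and counts the fraction through each
# intermediate node.  Independent of any library routine.
enumBetweenness <- function(A) {
  n <- nrow(A)
  pathsBetween <- function(s, t) {
    found <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { found[[length(found) + 1L]] <<- path; return(invisible()) }
      for (w in which(A[v, ] > 0)) if (!(w %in% path)) walk(c(path, w))
    }
    walk(s)
    found
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ps <- pathsBetween(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, length, integer(1))
    shortest <- ps[lens == min(lens)]
    sigma <- length(shortest)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(shortest, function(p)
        v %in% p[-c(1, length(p))], logical(1)))
      btw[v] <- btw[v] + through / sigma
    }
  }
  btw
}

# Brute-force sign-flip oracle for a single voxel: corrected p over all
# 2^n sign patterns, computed with plain t statistics.
bruteSignFlipP <- function(d) {
  n <- length(d)
  tOf <- function(x) mean(x) / (sd(x) / sqrt(n))
  tObs <- abs(tOf(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tAll <- abs(apply(signs, 1, function(s) tOf(s * d)))
  mean(tAll >= tObs - 1e-12)
}
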