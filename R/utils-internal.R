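# Internal numeric helpers shared across modules.  All voxel coordinates in
# here are 0-based and continuous; arrays are plain R arrays (1-based).

# Trilinear interpolation of a 3D array at continuous 0-based coordinates.
# pts: N x 3 matrix.  mode "zero": samples outside the grid take the value
# 0 (image resampling contract); mode "clamp": coordinates are clamped to
# the grid (used for displacement-field components, which are smooth and
# should not be dragged to zero at the edges).
trilinearSample <- function(arr, pts, mode = c("zero", "clamp")) {
  mode <- match.arg(mode)
  d <- dim(arr)
  if (mode == "clamp")
    for (k in 1:3) pts[, k] <- pmin(pmax(pts[, k], 0), d[k] - 1)
  # zero-pad by one voxel on every side so edge cells interpolate against 0
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- arr
  i0 <- floor(pts)
  f <- pts - i0
  out <- numeric(nrow(pts))
  valid <- i0[, 1] >= -1 & i0[, 1] <= d[1] - 1 &
           i0[, 2] >= -1 & i0[, 2] <= d[2] - 1 &
           i0[, 3] >= -1 & i0[, 3] <= d[3] - 1
  if (!any(valid)) return(out)
  i0 <- i0[valid, , drop = FALSE] + 2  # 1-based index into padded array
  f <- f[valid, , drop = FALSE]
  dp <- dim(pad)
  base <- i0[, 1] + dp[1] * (i0[, 2] - 1) + dp[1] * dp[2] * (i0[, 3] - 1)
  sx <- 1L; sy <- dp[1]; sz <- dp[1] * dp[2]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  acc <- pad[base]                  * (1 - fx) * (1 - fy) * (1 - fz) +
         pad[base + sx]             * fx       * (1 - fy) * (1 - fz) +
         pad[base + sy]             * (1 - fx) * fy       * (1 - fz) +
         pad[base + sx + sy]        * fx       * fy       * (1 - fz) +
         pad[base + sz]             * (1 - fx) * (1 - fy) * fz +
         pad[base + sx + sz]        * fx       * (1 - fy) * fz +
         pad[base + sy + sz]        * (1 - fx) * fy       * fz +
         pad[base + sx + sy + sz]   * fx       * fy       * fz
  out[valid] <- acc
  out
}

# Nearest-neighbour sampling (used for masks); outside the grid -> 0.
nearestSample <- function(arr, pts) {
  d <- dim(arr)
  i <- round(pts)
  out <- numeric(nrow(pts))
  valid <- i[, 1] >= 0 & i[, 1] <= d[1] - 1 &
           i[, 2] >= 0 & i[, 2] <= d[2] - 1 &
           i[, 3] >= 0 & i[, 3] <= d[3] - 1
  if (!any(valid)) return(out)
  iv <- i[valid, , drop = FALSE] + 1
  out[valid] <- arr[iv[, 1] + d[1] * (iv[, 2] - 1) + d[1] * d[2] * (iv[, 3] - 1)]
  out
}

# 0-based continuous voxel coordinates of every voxel of a grid, N x 3,
# column-major order (matching as.vector of the array).
gridCoords <- function(d) {
  cbind(rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
        rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

# Half-sample 'reflect' boundary index: maps any integer index (1-based,
# possibly out of range) back into 1..n by mirroring at the edges.
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep.int(1L, length(i)))
  p <- (i - 1L) %% (2L * n)
  ifelse(p < n, p + 1L, 2L * n - p)
}

# 1D Gaussian kernel, sigma in samples, truncated at 4 sigma, normalised.
gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Smoothing matrix for one axis under reflect boundaries.  Symmetric, rows
# and columns sum to 1, so the global mean is preserved exactly.
smoothMatrix1d <- function(n, sigma) {
  k <- gaussKernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  A <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in -r:r) {
    j <- reflectIndex(idx + o, n)
    A[cbind(idx, j)] <- A[cbind(idx, j)] + k[o + r + 1L]
  }
  A
}

# Separable Gaussian smoothing of a 3D array; sigmaVox per axis (voxels).
sepGaussSmooth <- function(arr, sigmaVox) {
  d <- dim(arr)
  x <- arr
  if (sigmaVox[1] > 0) {
    A <- smoothMatrix1d(d[1], sigmaVox[1])
    x <- array(A %*% matrix(x, d[1]), d)
  }
  if (sigmaVox[2] > 0) {
    A <- smoothMatrix1d(d[2], sigmaVox[2])
    x <- aperm(array(A %*% matrix(aperm(x, c(2, 1, 3)), d[2]),
                     d[c(2, 1, 3)]), c(2, 1, 3))
  }
  if (sigmaVox[3] > 0) {
    A <- smoothMatrix1d(d[3], sigmaVox[3])
    x <- aperm(array(A %*% matrix(aperm(x, c(3, 1, 2)), d[3]),
                     d[c(3, 1, 2)]), c(2, 3, 1))
  }
  x
}

# Central-difference gradient of a 3D array (replicated edges), in
# intensity per voxel; returns a 4D array (x, y, z, 3).
gradient3 <- function(arr) {
  d <- dim(arr)
  g <- array(0, c(d, 3L))
  ip <- pmin(seq_len(d[1]) + 1L, d[1]); im <- pmax(seq_len(d[1]) - 1L, 1L)
  g[, , , 1] <- (arr[ip, , , drop = FALSE] - arr[im, , , drop = FALSE]) /
    pmax(ip - im, 1L)
  ip <- pmin(seq_len(d[2]) + 1L, d[2]); im <- pmax(seq_len(d[2]) - 1L, 1L)
  g[, , , 2] <- (arr[, ip, , drop = FALSE] - arr[, im, , drop = FALSE]) /
    rep(pmax(ip - im, 1L), each = d[1])
  ip <- pmin(seq_len(d[3]) + 1L, d[3]); im <- pmax(seq_len(d[3]) - 1L, 1L)
  g[, , , 3] <- (arr[, , ip, drop = FALSE] - arr[, , im, drop = FALSE]) /
    rep(pmax(ip - im, 1L), each = d[1] * d[2])
  g
}

# Row-wise medians of an n x k matrix via a single order() pass.
rowMedians_ <- function(X) {
  if (is.null(dim(X))) return(X)
  n <- nrow(X); k <- ncol(X)
  if (k == 1L) return(X[, 1])
  ord <- matrix(X[order(row(X), X)], n, k, byrow = TRUE)
  if (k %% 2L == 1L) ord[, (k + 1L) %/% 2L]
  else (ord[, k %/% 2L] + ord[, k %/% 2L + 1L]) / 2
}

# Connected components of a logical 3D array under 26-connectivity.
# Returns an integer array (0 = background, 1..K component labels, labelled
# in decreasing size order).
connComp26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  inMask <- array(FALSE, d); inMask[idx] <- TRUE
  coord <- arrayInd(idx, d)
  pos <- array(0L, d); pos[idx] <- seq_along(idx)
  edges <- NULL
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  eList <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- coord + matrix(offs[k, ], nrow(coord), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    ni <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    hit <- inMask[ni]
    if (!any(hit)) next
    eList[[k]] <- cbind(pos[idx[ok]][hit], pos[ni[hit]])
  }
  edges <- do.call(rbind, eList)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  cmp <- igraph::components(g)
  sizes <- cmp$csize
  relabel <- integer(length(sizes))
  relabel[order(sizes, decreasing = TRUE)] <- seq_along(sizes)
  lab[idx] <- relabel[cmp$membership]
  lab
}

# Percentile with linear interpolation (type 7), used for all IQR reporting.
pctl <- function(x, p) unname(stats::quantile(x, p, type = 7))

sameGrid <- function(a, b, tol = 1e-6) {
  isTRUE(all(gridDim(a) == gridDim(b))) &&
    max(abs(affine(a) - affine(b))) < tol
}

stopIfDifferentGrid <- function(a, b, what = "inputs") {
  if (!sameGrid(a, b))
    stop(what, " must share one grid (same dimensions and affine)",
         call. = FALSE)
  invisible(TRUE)
}
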