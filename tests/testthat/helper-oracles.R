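# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (direct scans and closed forms only).

# brute-force squared distance to the nearest background voxel center,
# treating everything outside the grid as background
bruteEdt2 <- function(mask) {
  d <- dim(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- array(0, d)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    best <- min(p[1], d[1] + 1 - p[1], p[2], d[2] + 1 - p[2],
                p[3], d[3] + 1 - p[3])^2
    if (nrow(bg))
      best <- min(best, min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2 +
                              (bg[, 3] - p[3])^2))
    out[p[1], p[2], p[3]] <- best
  }
  out
}

# brute-force local thickness: every phase voxel is tried as a sphere
# center with radius sqrt(bruteEdt2) - 0.5; every covered voxel records the
# largest covering diameter
bruteLocalThickness <- function(mask) {
  d <- dim(mask)
  e2 <- bruteEdt2(mask)
  th <- array(0, d)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    rad <- sqrt(e2[p[1], p[2], p[3]]) - 0.5
    if (rad < 0) rad <- 0
    dia <- 2 * rad
    cover <- (idx[, 1] - p[1])^2 + (idx[, 2] - p[2])^2 +
      (idx[, 3] - p[3])^2 <= rad^2 + 1e-9
    sel <- idx[cover, , drop = FALSE]
    old <- th[sel]
    th[sel] <- pmax(old, dia)
  }
  th
}

# sign-scan root localization for tan(q) = -alpha*q on ((2n-1)pi/2, n*pi)
bruteCrankRoots <- function(alpha, nTerms, gridN = 1e6) {
  vapply(seq_len(nTerms), function(n) {
    qs <- seq((2 * n - 1) * pi / 2 + 1e-9, n * pi - 1e-9,
              length.out = gridN)
    f <- sin(qs) + alpha * qs * cos(qs)
    i <- which(f[-1] * f[-gridN] <= 0)[1]
    (qs[i] + qs[i + 1]) / 2
  }, numeric(1))
}

# fixture smoothing (not under test; just shapes random masks)
gaussianBlurRef <- function(x, sigma) porolith:::gaussianBlur3d(x, sigma)

# a digitized ball with its center on a voxel center
digitizedBall <- function(n, radius) {
  cc <- (n + 1) / 2
  arr <- array(0L, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    if ((i - cc)^2 + (j - cc)^2 + (k - cc)^2 <= radius^2) arr[i, j, k] <- 1L
  arr
}
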