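# Internal numerical helpers: coordinate grids, FFT filtering, local maxima,
# dart-throwing placement. All lengths nm unless noted.

# voxel-centre coordinates (nm) along one axis; 0-based index + 0.5 convention
.axisCoords <- function(n, vsNm) (seq_len(n) - 0.5) * vsNm

.volCoords <- function(vol) {
  d <- dim(densities(vol))
  vs <- voxelSizeNm(vol)
  list(x = .axisCoords(d[1], vs), y = .axisCoords(d[2], vs),
       z = .axisCoords(d[3], vs))
}

.clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# frequency coordinates (cycles per nm) for an axis of length n
.freqAxis <- function(n, vsNm) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  k / (n * vsNm)
}

# |k|^2 array for a 3D volume, cycles^2/nm^2
.freqSq <- function(d, vsNm) {
  kx <- .freqAxis(d[1], vsNm)^2
  ky <- .freqAxis(d[2], vsNm)^2
  kz <- .freqAxis(d[3], vsNm)^2
  outer(outer(kx, ky, "+"), kz, "+")
}

# FFT Gaussian smoothing (periodic boundaries; volumes have quiet borders)
.gaussianSmooth <- function(arr, sigmaNm, vsNm) {
  if (sigmaNm <= 0) return(arr)
  k2 <- .freqSq(dim(arr), vsNm)
  h <- exp(-2 * pi^2 * sigmaNm^2 * k2)
  Re(fft(fft(arr) * h, inverse = TRUE)) / length(arr)
}

# scale-normalized Laplacian-of-Gaussian response sigma^2 * Lap(G * I);
# positive at dark-blob centres (the Laplacian flips the dark dip's sign)
.logResponse <- function(arr, sigmaNm, vsNm) {
  k2 <- .freqSq(dim(arr), vsNm)
  h <- -(2 * pi)^2 * k2 * sigmaNm^2 * exp(-2 * pi^2 * sigmaNm^2 * k2)
  Re(fft(fft(arr) * h, inverse = TRUE)) / length(arr)
}

# strict 26-neighbourhood local maxima of a 3D array above a threshold;
# returns integer matrix of array indices (one row per maximum)
.localMaxima3d <- function(arr, threshold) {
  d <- dim(arr)
  cand <- arr > threshold
  if (!any(cand)) return(matrix(integer(0), ncol = 3))
  sh <- function(di, dj, dk) {
    ii <- .clamp(seq_len(d[1]) + di, 1L, d[1])
    jj <- .clamp(seq_len(d[2]) + dj, 1L, d[2])
    kk <- .clamp(seq_len(d[3]) + dk, 1L, d[3])
    arr[ii, jj, kk]
  }
  isMax <- cand
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    if (!any(isMax)) break
    isMax <- isMax & (arr >= sh(di, dj, dk))
  }
  which(isMax, arr.ind = TRUE)
}

# greedy dart-throwing placement of n points in a disc of radius r about
# (cx, cy) with minimum pairwise spacing, optionally rejecting positions
# where ok(x, y) is FALSE. Returns a 2-column matrix or NULL on failure.
.dartThrow <- function(n, cx, cy, r, minSpacing, ok = NULL,
                       maxAttempts = 8000L) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  px <- numeric(n); py <- numeric(n)
  placed <- 0L
  for (att in seq_len(maxAttempts)) {
    th <- runif(1, 0, 2 * pi)
    rr <- r * sqrt(runif(1))
    x <- cx + rr * cos(th); y <- cy + rr * sin(th)
    if (!is.null(ok) && !ok(x, y)) next
    if (placed > 0L) {
      d2 <- (px[seq_len(placed)] - x)^2 + (py[seq_len(placed)] - y)^2
      if (any(d2 < minSpacing^2)) next
    }
    placed <- placed + 1L
    px[placed] <- x; py[placed] <- y
    if (placed == n) return(cbind(px, py))
  }
  NULL
}

# connected components (6-connectivity) of a logical 3D mask; returns a list
# of integer index matrices (arr.ind), one per component
.connectedComponents3d <- function(mask) {
  d <- dim(mask)
  n1 <- d[1]; n12 <- d[1] * d[2]
  lab <- array(0L, d)
  comps <- list()
  nlab <- 0L
  for (start in which(mask)) {
    if (lab[start]) next
    nlab <- nlab + 1L
    lab[start] <- nlab
    frontier <- start
    members <- start
    while (length(frontier)) {
      ai <- arrayInd(frontier, d)
      nbr <- rbind(
        cbind(ai[, 1] - 1L, ai[, 2], ai[, 3]),
        cbind(ai[, 1] + 1L, ai[, 2], ai[, 3]),
        cbind(ai[, 1], ai[, 2] - 1L, ai[, 3]),
        cbind(ai[, 1], ai[, 2] + 1L, ai[, 3]),
        cbind(ai[, 1], ai[, 2], ai[, 3] - 1L),
        cbind(ai[, 1], ai[, 2], ai[, 3] + 1L))
      keep <- nbr[, 1] >= 1L & nbr[, 1] <= d[1] &
              nbr[, 2] >= 1L & nbr[, 2] <= d[2] &
              nbr[, 3] >= 1L & nbr[, 3] <= d[3]
      nbr <- nbr[keep, , drop = FALSE]
      lin <- unique(nbr[, 1] + (nbr[, 2] - 1L) * n1 + (nbr[, 3] - 1L) * n12)
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- nlab
      members <- c(members, lin)
      frontier <- lin
    }
    comps[[nlab]] <- arrayInd(members, d)
  }
  comps
}

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

# round half away from zero (printed-table convention)
.roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

.unitRows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  m / nrm
}
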