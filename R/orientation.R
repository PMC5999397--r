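# Preferred-orientation statistics on the sphere and the orientation
# coverage gained by collecting with intentional stage tilts.

#' Dispersion statistics of orientation axes
#'
#' Computes the mean resultant length R = |sum v| / n (or the axial
#' analogue (3 lambda_max - 1) / 2 of the orientation-matrix spectrum when
#' vectors are sign-ambiguous), clusters the directions by single-linkage
#' at an angular bandwidth, and maps R to an apparent-preferred-orientation
#' class: R < 0.2 none, 0.2-0.6 some, > 0.6 strong (the survey table's
#' No / Some / Yes). Thresholds are conventions and configurable.
#'
#' @param vectors n x 3 matrix of unit vectors (checked to 1e-6).
#' @param axial treat vectors as sign-ambiguous axes.
#' @param bandwidth clustering bandwidth, degrees.
#' @param thresholds numeric(2), the none/some and some/strong R cuts.
#' @return An \linkS4class{OrientationStats}.
#' @examples
#' v <- matrix(rep(c(0, 0, 1), 5), ncol = 3, byrow = TRUE)
#' orientationDispersion(v)  # R = 1, strong
#' @export
orientationDispersion <- function(vectors, axial = FALSE, bandwidth = 15,
                                  thresholds = c(0.2, 0.6)) {
  v <- matrix(as.numeric(as.matrix(vectors)), ncol = 3)
  n <- nrow(v)
  stopifnot(n >= 1)
  nrm <- sqrt(rowSums(v^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("orientation vectors must be unit norm")
  R <- if (axial) {
    S <- crossprod(v) / n
    (3 * max(eigen(S, symmetric = TRUE, only.values = TRUE)$values) - 1) / 2
  } else {
    sqrt(sum(colSums(v)^2)) / n
  }
  cl <- .sphereCluster(v, bandwidth, axial = axial)
  class <- if (R < thresholds[1]) "none"
           else if (R <= thresholds[2]) "some" else "strong"
  new("OrientationStats", n = as.integer(n), R = max(0, min(1, R)),
      axial = axial, modeCount = as.integer(length(cl$weights)),
      modes = cl$modes, weights = cl$weights, dispersionClass = class)
}

# single-linkage clustering on the sphere at an angular threshold
.sphereCluster <- function(v, bandwidth, axial = FALSE) {
  n <- nrow(v)
  cosb <- cos(.deg2rad(bandwidth))
  G <- tcrossprod(v)
  if (axial) G <- abs(G)
  adj <- G >= cosb
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i]) next
    cur <- cur + 1L
    frontier <- i
    lab[i] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & lab == 0L)
      lab[nb] <- cur
      frontier <- nb
    }
  }
  k <- max(lab)
  modes <- matrix(0, k, 3)
  w <- numeric(k)
  for (c0 in seq_len(k)) {
    m <- v[lab == c0, , drop = FALSE]
    if (axial && nrow(m) > 1) {
      # align signs to the first member before averaging
      sgn <- sign(m %*% m[1, ]); sgn[sgn == 0] <- 1
      m <- m * as.numeric(sgn)
    }
    mu <- colMeans(m)
    nm <- sqrt(sum(mu^2))
    modes[c0, ] <- if (nm > 1e-12) mu / nm else c(0, 0, 1)
    w[c0] <- nrow(m) / n
  }
  ord <- order(-w)
  list(modes = modes[ord, , drop = FALSE], weights = w[ord])
}

#' Projection-orientation coverage under a tilt scheme
#'
#' For a particle with preferred orientation modes and C_n symmetry about
#' the beam axis, collecting at a set of stage tilts turns each mode into
#' an annulus of imaged directions (in-plane rotation marginalized). The
#' function replicates the modes under the cyclic symmetry, sweeps each
#' tilt annulus, and returns the fraction of the projection hemisphere
#' covered within the angular bandwidth, integrated on an equal-area
#' Fibonacci grid.
#'
#' @param modes matrix (rows = unit mode directions) or a single vector.
#' @param symmetryOrder cyclic symmetry order (>= 1).
#' @param tilts stage tilt angles, degrees, each in [0, 90).
#' @param bandwidth angular bandwidth, degrees.
#' @param nGrid hemisphere grid points.
#' @return covered fraction of the hemisphere, in [0, 1].
#' @examples
#' tiltExpandedCoverage(c(0, 0, 1), 1, tilts = 0, bandwidth = 5)
#' @export
tiltExpandedCoverage <- function(modes, symmetryOrder = 1L, tilts = 0,
                                 bandwidth = 5, nGrid = 20000L) {
  m <- matrix(as.numeric(as.matrix(modes)), ncol = 3)
  if (nrow(m) == 0) stop("empty mode list")
  stopifnot(symmetryOrder >= 1, all(tilts >= 0), all(tilts < 90))
  m <- .unitRows(m)
  # replicate under C_n about the beam (z) axis
  reps <- do.call(rbind, lapply(seq_len(symmetryOrder) - 1L, function(j) {
    a <- 2 * pi * j / symmetryOrder
    rot <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    m %*% rot
  }))
  # fold onto the upper hemisphere (projection directions are axes)
  flip <- reps[, 3] < 0
  reps[flip, ] <- -reps[flip, , drop = FALSE]
  g <- .fibonacciHemisphere(nGrid)
  ang <- acos(.clamp(abs(g %*% t(reps)), 0, 1))  # grid x mode angles
  bw <- .deg2rad(bandwidth)
  covered <- rep(FALSE, nrow(g))
  for (t0 in .deg2rad(tilts)) {
    covered <- covered | apply(abs(ang - t0) <= bw, 1, any)
    if (all(covered)) break
  }
  mean(covered)
}

# near-equal-area point set on the upper hemisphere
.fibonacciHemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # uniform in z on [0, 1] = equal area
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}
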