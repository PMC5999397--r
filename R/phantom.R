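# Synthetic grid-hole phantom generator. Produces a TomoVolume plus a
# GroundTruth sidecar covering the ice-curvature (C1-C4), particle-behavior
# (B1-B5) and interface (A/A2) taxonomy, so every downstream measurement can
# be validated against known truth.

.PHANTOM_ICE_DENSITY <- -0.3       # vitreous ice vs vacuum background (0)
.PHANTOM_PARTICLE_DENSITY <- -1.0  # added on top of ice
.PHANTOM_CONTAM_DENSITY <- -0.8
.PHANTOM_FRAGMENT_DENSITY <- -0.7
.HEX_PACKING <- 0.9069             # hexagonal disc packing limit

#' Build a phantom configuration
#'
#' Assembles and validates a \linkS4class{PhantomConfig}. The two
#' interfaces are radially symmetric quadratic profiles in hole-centred
#' coordinates (offset from the volume mid-plane interpolating from
#' \code{center} to \code{edge} with \code{(r/R)^2}, clamped beyond the
#' rim), with a rigid plane tilt applied to both afterwards. Local ice
#' thickness is the sum of the two offsets, so e.g.
#' \code{center = 15, edge = 50} on both sides gives 30 nm centre / 100 nm
#' edge ice.
#'
#' Defaults emulate a typical screening tomogram: a 1.2 µm-class hole
#' imaged at bin-4 pixel size, 10 nm particles adsorbed 5 nm from the
#' interfaces with 90\% adsorption, a few-degree interface tilt, and
#' moderate noise.
#'
#' @param volumeShape integer(3) voxels (x, y, z).
#' @param voxelSize ångström.
#' @param holeRadius nm.
#' @param bottomProfile,topProfile list(class, center, edge); class in
#'   C1-C4, offsets in nm.
#' @param interfaceTilt degrees.
#' @param particleDiameter minor axis, nm.
#' @param aspectRatio ellipsoid long/minor axis ratio.
#' @param nParticles count; \code{adsorbedFraction} of them go to layers.
#' @param adsorbedFraction 0-1.
#' @param layerOffset nm from interface to adsorbed particle centre (0-10).
#' @param layerSplit fraction of adsorbed particles on the bottom surface.
#' @param orientationModel list(type = "uniform") or list(type = "modes",
#'   directions, kappa, weights).
#' @param saturationCap percent; requests beyond it are rejected.
#' @param nFreeParticles additional non-adsorbed particles.
#' @param contaminationDensity blobs per µm² per surface.
#' @param fragmentDensity debris blobs per µm² per interface.
#' @param noiseSigma density units.
#' @param missingWedge logical.
#' @param wedgeTiltRange retained half-range, degrees.
#' @param seed integer.
#' @return A validated \linkS4class{PhantomConfig}.
#' @examples
#' cfg <- phantomConfig(nParticles = 50L, noiseSigma = 0)
#' @export
phantomConfig <- function(volumeShape = c(144L, 144L, 96L),
                          voxelSize = 16,
                          holeRadius = 100,
                          bottomProfile = list(class = "C3", center = 15, edge = 50),
                          topProfile = list(class = "C3", center = 15, edge = 50),
                          interfaceTilt = 4,
                          particleDiameter = 10,
                          aspectRatio = 1,
                          nParticles = 200L,
                          adsorbedFraction = 0.9,
                          layerOffset = 5,
                          layerSplit = 0.5,
                          orientationModel = list(type = "uniform"),
                          saturationCap = 100,
                          nFreeParticles = 0L,
                          contaminationDensity = 0,
                          fragmentDensity = 0,
                          noiseSigma = 0.2,
                          missingWedge = FALSE,
                          wedgeTiltRange = 45,
                          seed = 1L) {
  cfg <- new("PhantomConfig",
    volumeShape = as.integer(volumeShape), voxelSize = as.numeric(voxelSize),
    holeRadius = as.numeric(holeRadius), bottomProfile = bottomProfile,
    topProfile = topProfile, interfaceTilt = as.numeric(interfaceTilt),
    particleDiameter = as.numeric(particleDiameter),
    aspectRatio = as.numeric(aspectRatio), nParticles = as.integer(nParticles),
    adsorbedFraction = as.numeric(adsorbedFraction),
    layerOffset = as.numeric(layerOffset), layerSplit = as.numeric(layerSplit),
    orientationModel = orientationModel,
    saturationCap = as.numeric(saturationCap),
    nFreeParticles = as.integer(nFreeParticles),
    contaminationDensity = as.numeric(contaminationDensity),
    fragmentDensity = as.numeric(fragmentDensity),
    noiseSigma = as.numeric(noiseSigma),
    missingWedge = isTRUE(missingWedge),
    wedgeTiltRange = as.numeric(wedgeTiltRange), seed = as.integer(seed))
  .validatePhantomConfig(cfg)
  cfg
}

.profileOffset <- function(profile, r, R) {
  f <- pmin(r / R, 1)^2
  profile$center + (profile$edge - profile$center) * f
}

.validatePhantomConfig <- function(cfg) {
  stopifnot(length(cfg@volumeShape) == 3L, all(cfg@volumeShape > 0L))
  vs <- cfg@voxelSize / 10
  fov <- cfg@volumeShape * vs
  if (cfg@holeRadius > min(fov[1], fov[2]) / 2)
    stop("infeasible config: holeRadius ", cfg@holeRadius,
         " nm does not fit the ", round(min(fov[1], fov[2])),
         " nm field of view")
  for (p in list(cfg@bottomProfile, cfg@topProfile)) {
    if (!is.list(p) || !all(c("class", "center", "edge") %in% names(p)))
      stop("profiles must be list(class, center, edge)")
    if (!p$class %in% c("C1", "C2", "C3", "C4"))
      stop("curvature class must be one of C1..C4")
    ok <- switch(p$class,
      C1 = p$center > p$edge, C2 = p$center == p$edge,
      C3 = , C4 = p$center < p$edge)
    if (!ok) stop("profile offsets inconsistent with curvature class ", p$class)
  }
  tCenter <- cfg@bottomProfile$center + cfg@topProfile$center
  if ((cfg@bottomProfile$class == "C4" || cfg@topProfile$class == "C4") &&
      tCenter >= cfg@particleDiameter)
    stop("C4 requires centre thickness (", tCenter,
         " nm) below the particle minor axis (", cfg@particleDiameter, " nm)")
  tMax <- max(cfg@bottomProfile$center + cfg@topProfile$center,
              cfg@bottomProfile$edge + cfg@topProfile$edge)
  tiltSpan <- tan(.deg2rad(cfg@interfaceTilt)) * fov[1]
  if (1.2 * tMax + tiltSpan > fov[3])
    stop("infeasible config: max ice thickness ", tMax,
         " nm (+20% margin and tilt) exceeds the ", round(fov[3]),
         " nm z extent")
  if (cfg@adsorbedFraction < 0 || cfg@adsorbedFraction > 1)
    stop("adsorbedFraction must lie in [0, 1]")
  if (cfg@layerOffset < 0 || cfg@layerOffset > 10)
    stop("layerOffset must lie in [0, 10] nm")
  if (cfg@saturationCap <= 0 || cfg@saturationCap > 100)
    stop("saturationCap must lie in (0, 100]")
  # packing feasibility per layer at the saturation cap
  nAds <- round(cfg@nParticles * cfg@adsorbedFraction)
  nBottom <- round(nAds * cfg@layerSplit)
  area <- pi * cfg@holeRadius^2
  foot <- pi * (cfg@particleDiameter / 2)^2
  capN <- floor(cfg@saturationCap / 100 * .HEX_PACKING * area / foot)
  if (max(nBottom, nAds - nBottom) > capN)
    stop("infeasible config: requested ", max(nBottom, nAds - nBottom),
         " particles in one layer but the saturation cap of ",
         cfg@saturationCap, "% admits at most ", capN)
  invisible(TRUE)
}

.surfaceAnalytic <- function(cfg, side) {
  vs <- cfg@voxelSize / 10
  fov <- cfg@volumeShape * vs
  prof <- if (side == "bottom") cfg@bottomProfile else cfg@topProfile
  list(side = side, z0 = fov[3] / 2,
       centerOffset = prof$center, edgeOffset = prof$edge,
       holeRadius = cfg@holeRadius,
       slopeX = tan(.deg2rad(cfg@interfaceTilt)), slopeY = 0,
       cx = fov[1] / 2, cy = fov[2] / 2)
}

# evaluate an analytic surface at (x, y); vectors or grid
.surfaceZ <- function(s, x, y, grid = FALSE) {
  if (grid) {
    r2 <- outer((x - s$cx)^2, (y - s$cy)^2, "+")
    off <- s$centerOffset + (s$edgeOffset - s$centerOffset) *
      pmin(sqrt(r2) / s$holeRadius, 1)^2
    tiltTerm <- outer(s$slopeX * (x - s$cx), s$slopeY * (y - s$cy), "+")
  } else {
    r <- sqrt((x - s$cx)^2 + (y - s$cy)^2)
    off <- s$centerOffset + (s$edgeOffset - s$centerOffset) *
      pmin(r / s$holeRadius, 1)^2
    tiltTerm <- s$slopeX * (x - s$cx) + s$slopeY * (y - s$cy)
  }
  if (s$side == "bottom") s$z0 - off + tiltTerm else s$z0 + off + tiltTerm
}

#' Convert an analytic phantom surface to an InterfaceSurface
#'
#' Ground-truth surfaces carry their exact analytic form; this re-expresses
#' one in the fitted-surface model (plane + radial quadratic) used by the
#' geometry module, e.g. to drive \code{\link{thicknessStats}} directly
#' from truth.
#'
#' @param s one element of the \code{surfaces} slot of a
#'   \linkS4class{GroundTruth}.
#' @return An \linkS4class{InterfaceSurface} with locator "analytic".
#' @export
analyticInterface <- function(s) {
  sgn <- if (s$side == "bottom") -1 else 1
  q <- sgn * (s$edgeOffset - s$centerOffset) / s$holeRadius^2
  cc <- s$z0 + sgn * s$centerOffset - s$slopeX * s$cx - s$slopeY * s$cy
  new("InterfaceSurface", side = s$side, a = s$slopeX, b = s$slopeY,
      c = cc, q = q, x0 = s$cx, y0 = s$cy, order = 2L,
      fitResidual = 0, locator = "analytic", supportPoints = 0L)
}

#' Sample particle orientation axes
#'
#' Draws unit vectors from the configured orientation model: "uniform" on
#' the sphere, or a mixture of von Mises-Fisher modes ("modes", with
#' \code{directions} (rows), \code{kappa} concentration(s) and optional
#' \code{weights}).
#'
#' @param model orientation model list (see \code{\link{phantomConfig}}).
#' @param n number of vectors (>= 1).
#' @param seed optional integer; when given, seeds the RNG locally.
#' @return n x 3 matrix of unit vectors (unit norm within 1e-9).
#' @examples
#' v <- sampleOrientations(list(type = "uniform"), 100, seed = 1)
#' max(abs(sqrt(rowSums(v^2)) - 1)) < 1e-9
#' @export
sampleOrientations <- function(model, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (identical(model$type, "uniform")) {
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    return(.unitRows(v))
  }
  if (!identical(model$type, "modes"))
    stop("unknown orientation model type: ", model$type)
  dirs <- model$directions
  if (is.null(dirs) || NROW(dirs) == 0L)
    stop("non-uniform orientation model with empty mode list")
  dirs <- .unitRows(matrix(dirs, ncol = 3))
  k <- rep_len(model$kappa, nrow(dirs))
  if (any(k < 0)) stop("concentrations must be >= 0")
  w <- model$weights
  if (is.null(w)) w <- rep(1, nrow(dirs))
  w <- w / sum(w)
  comp <- sample.int(nrow(dirs), n, replace = TRUE, prob = w)
  out <- matrix(0, n, 3)
  for (i in seq_len(nrow(dirs))) {
    m <- comp == i
    if (!any(m)) next
    out[m, ] <- .rvmf(sum(m), dirs[i, ], k[i])
  }
  out
}

# von Mises-Fisher sampler on S2 (Ulrich/Wood inversion for p = 3)
.rvmf <- function(n, mu, kappa) {
  if (kappa < 1e-8) {
    return(.unitRows(matrix(stats::rnorm(3 * n), ncol = 3)))
  }
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  th <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  local <- cbind(s * cos(th), s * sin(th), w)
  # rotate z onto mu
  mu <- mu / sqrt(sum(mu^2))
  if (abs(mu[3] - 1) < 1e-12) return(local)
  if (abs(mu[3] + 1) < 1e-12) return(local %*% diag(c(1, -1, -1)))
  ax <- c(-mu[2], mu[1], 0); ax <- ax / sqrt(sum(ax^2))
  ang <- acos(mu[3])
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  t(Rm %*% t(local))
}

# add one soft-edged ellipsoid (minor axis d, long axis d*aspect along v)
# to arr in place-ish; returns modified arr
.renderEllipsoid <- function(arr, coords, center, d, aspect, v, amplitude,
                             vsNm, edgeNm) {
  rmax <- d / 2 * max(1, aspect) + 2 * edgeNm
  ix <- which(abs(coords$x - center[1]) <= rmax)
  iy <- which(abs(coords$y - center[2]) <= rmax)
  iz <- which(abs(coords$z - center[3]) <= rmax)
  if (!length(ix) || !length(iy) || !length(iz)) return(arr)
  dx <- coords$x[ix] - center[1]
  dy <- coords$y[iy] - center[2]
  dz <- coords$z[iz] - center[3]
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  X <- array(dx, c(nx, ny, nz))
  Y <- array(rep(dy, each = nx), c(nx, ny, nz))
  Z <- array(rep(dz, each = nx * ny), c(nx, ny, nz))
  # component along the long axis and perpendicular residual
  par <- X * v[1] + Y * v[2] + Z * v[3]
  perp2 <- pmax(0, X^2 + Y^2 + Z^2 - par^2)
  m <- sqrt((par / (aspect * d / 2))^2 + perp2 / (d / 2)^2)
  sdist <- (m - 1) * (d / 2)              # approximate signed distance, nm
  f <- .clamp(0.5 - sdist / edgeNm, 0, 1)
  arr[ix, iy, iz] <- arr[ix, iy, iz] + amplitude * f
  arr
}

#' Generate a synthetic grid-hole tomogram with ground truth
#'
#' Renders the configured hole: a vitreous-ice slab between two interfaces
#' (dark on a brighter vacuum background, standard cryoEM contrast),
#' soft-edged ellipsoid particles placed by dart-throwing with a minimum
#' spacing of one particle footprint (adsorbed layers at
#' \code{layerOffset} from each interface; free particles mid-ice at least
#' one particle radius from both), contamination blobs seated on the air
#' side of each interface, debris fragments just inside them, Gaussian
#' noise, and optionally a missing-wedge filter (Fourier coefficients
#' outside the retained tilt range about the x axis zeroed).
#'
#' Regions where the local ice is thinner than the particle minor axis
#' (C4) receive no whole particles. Output is deterministic in
#' (config, seed).
#'
#' @param cfg a \linkS4class{PhantomConfig}.
#' @return list(volume = \linkS4class{TomoVolume},
#'   truth = \linkS4class{GroundTruth}).
#' @examples
#' ph <- makePhantom(phantomConfig(nParticles = 20L, noiseSigma = 0))
#' ph$truth
#' @export
makePhantom <- function(cfg) {
  .validatePhantomConfig(cfg)
  set.seed(cfg@seed)
  vs <- cfg@voxelSize / 10
  d <- cfg@volumeShape
  coords <- list(x = .axisCoords(d[1], vs), y = .axisCoords(d[2], vs),
                 z = .axisCoords(d[3], vs))
  sb <- .surfaceAnalytic(cfg, "bottom")
  st <- .surfaceAnalytic(cfg, "top")
  zb <- .surfaceZ(sb, coords$x, coords$y, grid = TRUE)
  zt <- .surfaceZ(st, coords$x, coords$y, grid = TRUE)
  thick <- zt - zb

  # ice slab with anti-aliased (fractional-coverage) boundaries
  arr <- array(0, d)
  for (k in seq_len(d[3])) {
    zlo <- coords$z[k] - vs / 2
    zhi <- coords$z[k] + vs / 2
    cov <- .clamp((pmin(zt, zhi) - pmax(zb, zlo)) / vs, 0, 1)
    arr[, , k] <- .PHANTOM_ICE_DENSITY * cov
  }

  cx <- sb$cx; cy <- sb$cy
  dParticle <- cfg@particleDiameter
  nAds <- round(cfg@nParticles * cfg@adsorbedFraction)
  nBottom <- round(nAds * cfg@layerSplit)
  nTop <- nAds - nBottom
  nFree <- cfg@nParticles - nAds + cfg@nFreeParticles

  thickAt <- function(x, y) {
    .surfaceZ(st, x, y) - .surfaceZ(sb, x, y)
  }
  okThick <- function(x, y) thickAt(x, y) >= dParticle
  placeMargin <- dParticle / 2
  placeR <- min(cfg@holeRadius,
                min(d[1], d[2]) * vs / 2 - dParticle * max(1, cfg@aspectRatio))

  placeLayer <- function(n, side) {
    if (n == 0L) return(NULL)
    pts <- .dartThrow(n, cx, cy, placeR, minSpacing = dParticle, ok = okThick)
    if (is.null(pts))
      stop("infeasible config: could not place ", n, " particles in the ",
           side, " layer at saturation cap ", cfg@saturationCap,
           "% (packing bound violated)")
    z <- if (side == "bottom")
      .surfaceZ(sb, pts[, 1], pts[, 2]) + cfg@layerOffset
    else
      .surfaceZ(st, pts[, 1], pts[, 2]) - cfg@layerOffset
    data.frame(x = pts[, 1], y = pts[, 2], z = z, adsorbed = TRUE,
               side = side, layer = if (side == "bottom") 1L else 2L)
  }
  pb <- placeLayer(nBottom, "bottom")
  pt <- placeLayer(nTop, "top")

  pf <- NULL
  if (nFree > 0L) {
    fx <- numeric(nFree); fy <- numeric(nFree); fz <- numeric(nFree)
    got <- 0L; tries <- 0L
    while (got < nFree && tries < 20000L) {
      tries <- tries + 1L
      th <- stats::runif(1, 0, 2 * pi); rr <- placeR * sqrt(stats::runif(1))
      x <- cx + rr * cos(th); y <- cy + rr * sin(th)
      lo <- .surfaceZ(sb, x, y) + placeMargin
      hi <- .surfaceZ(st, x, y) - placeMargin
      if (hi <= lo) next
      got <- got + 1L
      fx[got] <- x; fy[got] <- y; fz[got] <- stats::runif(1, lo, hi)
    }
    if (got < nFree)
      stop("infeasible config: ice too thin for ", nFree,
           " non-adsorbed particles (needs > particle diameter of clearance)")
    pf <- data.frame(x = fx, y = fy, z = fz, adsorbed = FALSE,
                     side = "none", layer = NA_integer_)
  }
  particles <- rbind(pb, pt, pf)
  if (is.null(particles))
    particles <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                            adsorbed = logical(0), side = character(0),
                            layer = integer(0))

  nP <- nrow(particles)
  if (nP > 0) {
    nAdsReal <- sum(particles$adsorbed)
    vAds <- if (nAdsReal > 0)
      sampleOrientations(cfg@orientationModel, nAdsReal) else NULL
    vFree <- if (nP - nAdsReal > 0)
      sampleOrientations(list(type = "uniform"), nP - nAdsReal) else NULL
    v <- matrix(0, nP, 3)
    if (!is.null(vAds)) v[particles$adsorbed, ] <- vAds
    if (!is.null(vFree)) v[!particles$adsorbed, ] <- vFree
    particles$vx <- v[, 1]; particles$vy <- v[, 2]; particles$vz <- v[, 3]
    particles$diameter <- dParticle
    edgeNm <- 1.5 * vs
    for (i in seq_len(nP)) {
      arr <- .renderEllipsoid(arr, coords,
                              c(particles$x[i], particles$y[i], particles$z[i]),
                              dParticle, cfg@aspectRatio, v[i, ],
                              .PHANTOM_PARTICLE_DENSITY, vs, edgeNm)
    }
  } else {
    particles$vx <- numeric(0); particles$vy <- numeric(0)
    particles$vz <- numeric(0); particles$diameter <- numeric(0)
  }

  # surface contamination: spheres seated on the air side, face touching ice
  fovAreaUm2 <- (d[1] * vs / 1000) * (d[2] * vs / 1000)
  nContam <- stats::rpois(2, cfg@contaminationDensity * fovAreaUm2)
  contam <- NULL
  edgeNm <- 1.5 * vs
  for (sideI in 1:2) {
    if (nContam[sideI] == 0) next
    s <- if (sideI == 1) sb else st
    for (j in seq_len(nContam[sideI])) {
      rb <- stats::runif(1, 8, 18)
      th <- stats::runif(1, 0, 2 * pi)
      rr <- (cfg@holeRadius * 0.95) * sqrt(stats::runif(1))
      x <- cx + rr * cos(th); y <- cy + rr * sin(th)
      zc <- if (sideI == 1) .surfaceZ(s, x, y) - rb else .surfaceZ(s, x, y) + rb
      arr <- .renderEllipsoid(arr, coords, c(x, y, zc), 2 * rb, 1,
                              c(0, 0, 1), .PHANTOM_CONTAM_DENSITY, vs, edgeNm)
      contam <- rbind(contam, data.frame(x = x, y = y, z = zc, radius = rb,
                                         side = if (sideI == 1) "bottom" else "top"))
    }
  }

  # small protein-fragment debris just inside each interface
  nFrag <- stats::rpois(2, cfg@fragmentDensity * fovAreaUm2)
  for (sideI in 1:2) {
    if (nFrag[sideI] == 0) next
    s <- if (sideI == 1) sb else st
    for (j in seq_len(nFrag[sideI])) {
      rb <- stats::runif(1, 1, 2.5)
      th <- stats::runif(1, 0, 2 * pi)
      rr <- (cfg@holeRadius * 0.95) * sqrt(stats::runif(1))
      x <- cx + rr * cos(th); y <- cy + rr * sin(th)
      off <- stats::runif(1, rb, rb + 2)
      zc <- if (sideI == 1) .surfaceZ(s, x, y) + off else .surfaceZ(s, x, y) - off
      arr <- .renderEllipsoid(arr, coords, c(x, y, zc), 2 * rb, 1,
                              c(0, 0, 1), .PHANTOM_FRAGMENT_DENSITY, vs, edgeNm)
    }
  }

  if (cfg@noiseSigma > 0)
    arr <- arr + stats::rnorm(length(arr), 0, cfg@noiseSigma)
  if (cfg@missingWedge)
    arr <- .applyMissingWedge(arr, cfg@wedgeTiltRange)

  # realized statistics and taxonomy
  realizedAds <- if (cfg@nParticles > 0) nAds / cfg@nParticles else NA_real_
  area <- pi * cfg@holeRadius^2
  foot <- pi * (dParticle / 2)^2
  sat <- c(bottom = 100 * nBottom * foot / (area * .HEX_PACKING),
           top = 100 * nTop * foot / (area * .HEX_PACKING))
  aCode <- if (cfg@fragmentDensity > 0) "A2" else "A"
  bCodes <- character(0)
  if (nFree > 0) bCodes <- "B1"
  if (nAds > 0)
    bCodes <- c(bCodes,
                if (identical(cfg@orientationModel$type, "uniform")) "B2" else "B3")
  taxonomy <- list(interface = c(bottom = aCode, top = aCode),
                   behavior = bCodes,
                   curvature = c(bottom = cfg@bottomProfile$class,
                                 top = cfg@topProfile$class))
  truth <- new("GroundTruth",
    particles = particles, surfaces = list(bottom = sb, top = st),
    thicknessMap = thick, x = coords$x, y = coords$y,
    taxonomy = taxonomy,
    realizedAdsorbedFraction = realizedAds,
    realizedSaturation = sat, config = cfg, seed = cfg@seed)
  list(volume = TomoVolume(arr, cfg@voxelSize), truth = truth)
}

# zero Fourier coefficients outside the retained tilt range about the x axis
.applyMissingWedge <- function(arr, tiltRange) {
  d <- dim(arr)
  ky <- .freqAxis(d[2], 1)
  kz <- .freqAxis(d[3], 1)
  KY <- abs(outer(rep(1, d[1]), ky))
  keepYZ <- array(TRUE, c(d[1], d[2], d[3]))
  tanMax <- tan(.deg2rad(tiltRange))
  for (k in seq_len(d[3])) {
    keepYZ[, , k] <- abs(kz[k]) <= tanMax * KY + 1e-12
  }
  ft <- fft(arr) * keepYZ
  Re(fft(ft, inverse = TRUE)) / length(arr)
}

#' Write / read a phantom ground truth
#'
#' The sidecar is JSON (config, surfaces, realized statistics, taxonomy)
#' with the per-particle table embedded; \code{writeParticleCSV} exports
#' the particle truth table alone as CSV with columns
#' x_nm, y_nm, z_nm, vx, vy, vz, adsorbed, side, layer.
#' write/read round-trips losslessly.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path output path.
#' @return \code{path} invisibly; \code{readGroundTruth} returns the
#'   reconstructed \linkS4class{GroundTruth}.
#' @export
writeGroundTruth <- function(truth, path) {
  cfg <- truth@config
  obj <- list(
    seed = truth@seed,
    config = list(
      volumeShape = cfg@volumeShape, voxelSize = cfg@voxelSize,
      holeRadius = cfg@holeRadius, bottomProfile = cfg@bottomProfile,
      topProfile = cfg@topProfile, interfaceTilt = cfg@interfaceTilt,
      particleDiameter = cfg@particleDiameter, aspectRatio = cfg@aspectRatio,
      nParticles = cfg@nParticles, adsorbedFraction = cfg@adsorbedFraction,
      layerOffset = cfg@layerOffset, layerSplit = cfg@layerSplit,
      orientationModel = cfg@orientationModel,
      saturationCap = cfg@saturationCap, nFreeParticles = cfg@nFreeParticles,
      contaminationDensity = cfg@contaminationDensity,
      fragmentDensity = cfg@fragmentDensity, noiseSigma = cfg@noiseSigma,
      missingWedge = cfg@missingWedge, wedgeTiltRange = cfg@wedgeTiltRange,
      seed = cfg@seed),
    surfaces = truth@surfaces,
    taxonomy = lapply(truth@taxonomy, as.list),
    realizedAdsorbedFraction = truth@realizedAdsorbedFraction,
    realizedSaturation = as.list(truth@realizedSaturation),
    particles = truth@particles)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- obj$config
  om <- as.list(cf$orientationModel)
  if (!is.null(om$directions))
    om$directions <- matrix(unlist(om$directions), ncol = 3)
  cfg <- phantomConfig(
    volumeShape = cf$volumeShape, voxelSize = cf$voxelSize,
    holeRadius = cf$holeRadius, bottomProfile = as.list(cf$bottomProfile),
    topProfile = as.list(cf$topProfile), interfaceTilt = cf$interfaceTilt,
    particleDiameter = cf$particleDiameter, aspectRatio = cf$aspectRatio,
    nParticles = cf$nParticles, adsorbedFraction = cf$adsorbedFraction,
    layerOffset = cf$layerOffset, layerSplit = cf$layerSplit,
    orientationModel = om, saturationCap = cf$saturationCap,
    nFreeParticles = cf$nFreeParticles,
    contaminationDensity = cf$contaminationDensity,
    fragmentDensity = cf$fragmentDensity, noiseSigma = cf$noiseSigma,
    missingWedge = cf$missingWedge, wedgeTiltRange = cf$wedgeTiltRange,
    seed = cf$seed)
  part <- obj$particles
  if (length(part) == 0L || NROW(part) == 0L)
    part <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                       adsorbed = logical(0), side = character(0),
                       layer = integer(0), vx = numeric(0), vy = numeric(0),
                       vz = numeric(0), diameter = numeric(0))
  vs <- cfg@voxelSize / 10
  sb <- as.list(obj$surfaces$bottom); st <- as.list(obj$surfaces$top)
  x <- .axisCoords(cfg@volumeShape[1], vs)
  y <- .axisCoords(cfg@volumeShape[2], vs)
  thick <- .surfaceZ(st, x, y, grid = TRUE) - .surfaceZ(sb, x, y, grid = TRUE)
  tax <- obj$taxonomy
  new("GroundTruth", particles = as.data.frame(part),
      surfaces = list(bottom = sb, top = st),
      thicknessMap = thick, x = x, y = y,
      taxonomy = list(interface = unlist(tax$interface),
                      behavior = unlist(tax$behavior),
                      curvature = unlist(tax$curvature)),
      realizedAdsorbedFraction = if (is.null(obj$realizedAdsorbedFraction))
        NA_real_ else as.numeric(obj$realizedAdsorbedFraction),
      realizedSaturation = unlist(obj$realizedSaturation),
      config = cfg, seed = as.integer(obj$seed))
}

#' @rdname writeGroundTruth
#' @export
writeParticleCSV <- function(truth, path) {
  p <- truth@particles
  out <- data.frame(x_nm = p$x, y_nm = p$y, z_nm = p$z,
                    vx = p$vx, vy = p$vy, vz = p$vz,
                    adsorbed = p$adsorbed, side = p$side, layer = p$layer)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
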