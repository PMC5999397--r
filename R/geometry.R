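# Interface location, ice-thickness and tilt measurement, and curvature
# classification. Follows the standard tomogram measurement procedure:
# work on (optionally bin-4) volumes, locate each air-water interface from
# the density gradient, from surface contamination (the blob face nearest
# the vitreous ice anchors the surface) or from an adsorbed particle layer
# plus its known offset, then measure the inter-surface distance along z.

#' Per-slice density profile of a volume
#'
#' One robust density statistic (median) per z slice over the (x, y) mask,
#' used to find the ice slab along the beam axis.
#'
#' @param vol a \linkS4class{TomoVolume}.
#' @param mask logical nx x ny matrix; default all TRUE.
#' @return numeric vector of length nz.
#' @export
zProfile <- function(vol, mask = NULL) {
  arr <- densities(vol)
  d <- dim(arr)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!any(mask)) stop("empty mask")
  idx <- which(mask)
  vapply(seq_len(d[3]), function(k) {
    sl <- arr[, , k]
    stats::median(sl[idx])
  }, numeric(1))
}

# half-maximum crossings of a slab-shaped (dark) profile; returns subvoxel
# z positions (voxel units, 0-based + 0.5 centre convention) of the two
# outermost boundaries enclosing the densest slab, or NULL
.slabBounds <- function(profile) {
  n <- length(profile)
  bg <- stats::median(profile[c(1:max(1, n %/% 10),
                               (n - max(1, n %/% 10) + 1):n)])
  lo <- min(profile)
  if (bg - lo < 1e-12) return(NULL)
  # first pass: rough slab at the background/min midpoint; second pass:
  # re-level at the slab-interior median so dense particle layers inside
  # the ice do not drag the crossing level down
  half <- (bg + lo) / 2
  rough <- which(profile < half)
  if (length(rough) >= 3) {
    core <- rough[rough > min(rough) & rough < max(rough)]
    if (length(core) >= 2) {
      # the plateau is the *lightest* part of the slab interior: particle
      # layers and contamination are darker than the embedding ice
      ice <- stats::quantile(profile[core], 0.8, names = FALSE)
      half <- (bg + ice) / 2
    }
  }
  out <- .runCrossings(profile, half)
  if (!is.null(out)) attr(out, "half") <- half
  out
}

# outermost crossings of a fixed level: pick the below-level run with the
# lowest mean density (or, given a 1-based index interval refIdx, the
# largest overlap with it) and interpolate its two crossings to subvoxel
# z (0-based voxel-centre units)
.runCrossings <- function(profile, half, refIdx = NULL) {
  n <- length(profile)
  below <- profile < half
  if (!any(below)) return(NULL)
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  slabs <- which(runs$values)
  if (!length(slabs)) return(NULL)
  score <- if (is.null(refIdx)) {
    -vapply(slabs, function(i) mean(profile[starts[i]:ends[i]]), numeric(1))
  } else {
    vapply(slabs, function(i)
      max(0, min(ends[i], refIdx[2]) - max(starts[i], refIdx[1]) + 1),
      numeric(1))
  }
  if (!is.null(refIdx) && max(score) <= 0) return(NULL)
  i <- slabs[which.max(score)]
  i1 <- starts[i]; i2 <- ends[i]
  zLow <- if (i1 > 1) {
    f <- (profile[i1 - 1] - half) / (profile[i1 - 1] - profile[i1])
    (i1 - 1 - 0.5) + f
  } else i1 - 0.5
  zHigh <- if (i2 < n) {
    f <- (profile[i2] - half) / (profile[i2] - profile[i2 + 1])
    (i2 - 0.5) + (1 - f)
  } else i2 - 0.5
  c(zLow, zHigh)
}

#' Least-squares surface fit through 3D points
#'
#' Fits \code{z = a x + b y + c} (order 1) or the same plus a radially
#' symmetric quadratic term about the point centroid (order 2). The
#' residual is the RMS misfit in z.
#'
#' @param points matrix or data.frame with columns x, y, z (nm).
#' @param order 1 or 2.
#' @param side "bottom" or "top" label for the resulting surface.
#' @param locator provenance label.
#' @return An \linkS4class{InterfaceSurface}.
#' @examples
#' p <- cbind(x = c(0, 1, 0), y = c(0, 0, 1), z = c(10, 10, 10))
#' fitSurface(p)  # plane z = 10
#' @export
fitSurface <- function(points, order = 1L, side = "bottom",
                       locator = "gradient") {
  pts <- as.data.frame(points)
  names(pts)[1:3] <- c("x", "y", "z")
  need <- if (order == 2L) 4L else 3L
  if (nrow(pts) < need)
    stop("need at least ", need, " points for an order-", order, " fit")
  x0 <- mean(pts$x); y0 <- mean(pts$y)
  if (order == 2L) {
    pts$r2 <- (pts$x - x0)^2 + (pts$y - y0)^2
    fit <- stats::lm(z ~ x + y + r2, data = pts)
  } else {
    fit <- stats::lm(z ~ x + y, data = pts)
  }
  if (anyNA(stats::coef(fit)))
    stop("degenerate point configuration (collinear or coincident points)")
  co <- stats::coef(fit)
  res <- sqrt(mean(stats::residuals(fit)^2))
  new("InterfaceSurface", side = side,
      a = unname(co["x"]), b = unname(co["y"]),
      c = unname(co["(Intercept)"]),
      q = if (order == 2L) unname(co["r2"]) else 0,
      x0 = x0, y0 = y0, order = as.integer(order),
      fitResidual = res, locator = locator,
      supportPoints = nrow(pts))
}

#' @describeIn fitSurface tilt of the fitted plane component: absolute
#'   angle (degrees, in [0, 90)) between the surface normal and the beam
#'   axis; \code{arccos(1 / sqrt(1 + a^2 + b^2))}.
#' @aliases surfaceTilt,InterfaceSurface-method
#' @export surfaceTilt
setMethod("surfaceTilt", "InterfaceSurface", function(surface) {
  .rad2deg(acos(1 / sqrt(1 + surface@a^2 + surface@b^2)))
})

#' Locate the two air-water interfaces in a volume
#'
#' Three locator strategies:
#' \describe{
#'   \item{gradient}{find the dense slab in the z profile, then refine the
#'     two boundaries per (x, y) patch by subvoxel half-maximum crossings
#'     and fit an order-2 surface through them. When more than two
#'     boundary candidates appear, the outermost pair enclosing the
#'     densest slab is kept.}
#'   \item{contamination}{segment dark blobs outside the slab; each blob's
#'     face nearest the vitreous ice anchors its surface (>= 3 blobs per
#'     surface required); planes are fitted through the anchor points.}
#'   \item{particle_layer}{detect particles, split them into bottom/top
#'     layers, fit a plane per layer and shift it outward by the
#'     layer-offset \code{hint} (nm).}
#' }
#'
#' @param vol a \linkS4class{TomoVolume}.
#' @param strategy "gradient", "contamination" or "particle_layer".
#' @param hint layer offset in nm (particle_layer strategy).
#' @param mask optional logical nx x ny hole mask.
#' @param patches number of patches per axis for gradient refinement.
#' @param particleDiameter nm, for the particle_layer detector.
#' @return list(bottom, top) of \linkS4class{InterfaceSurface}.
#' @export
locateInterfaces <- function(vol, strategy = c("gradient", "contamination",
                                               "particle_layer"),
                             hint = NULL, mask = NULL, patches = 10L,
                             particleDiameter = 10) {
  strategy <- match.arg(strategy)
  switch(strategy,
    gradient = .locateGradient(vol, mask, patches),
    contamination = .locateContamination(vol, mask),
    particle_layer = .locateParticleLayer(vol, hint, particleDiameter))
}

.locateGradient <- function(vol, mask, patches) {
  arr <- densities(vol)
  d <- dim(arr)
  vs <- voxelSizeNm(vol)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  prof <- zProfile(vol, mask)
  glob <- .slabBounds(prof)
  if (is.null(glob))
    stop("fewer than 2 density boundaries found along z")
  # the global (median-over-columns) profile suppresses particles, so its
  # half level is a robust crossing level for every column
  half <- attr(glob, "half")
  globIdx <- c(floor(glob[1] + 1), ceiling(glob[2] + 1))
  # lateral smoothing stabilizes per-column crossings without moving them
  sm <- .lateralSmooth(arr, 1.5)
  xs <- .axisCoords(d[1], vs); ys <- .axisCoords(d[2], vs)
  cols <- which(mask, arr.ind = TRUE)
  stride <- max(1L, ceiling(sqrt(nrow(cols) / 4000)))
  keep <- cols[, 1] %% stride == 0L & cols[, 2] %% stride == 0L
  cols <- cols[keep, , drop = FALSE]
  ptsB <- matrix(NA_real_, nrow(cols), 3)
  ptsT <- ptsB
  for (i in seq_len(nrow(cols))) {
    b <- .runCrossings(sm[cols[i, 1], cols[i, 2], ], half, refIdx = globIdx)
    if (is.null(b)) next
    ptsB[i, ] <- c(xs[cols[i, 1]], ys[cols[i, 2]], b[1] * vs)
    ptsT[i, ] <- c(xs[cols[i, 1]], ys[cols[i, 2]], b[2] * vs)
  }
  ptsB <- ptsB[stats::complete.cases(ptsB), , drop = FALSE]
  ptsT <- ptsT[stats::complete.cases(ptsT), , drop = FALSE]
  if (nrow(ptsB) < 6 || nrow(ptsT) < 6)
    stop("too few refined boundary points for a surface fit")
  bot <- .robustSurfaceFit(ptsB, side = "bottom")
  top <- .robustSurfaceFit(ptsT, side = "top")
  if (bot@c >= top@c) stop("bottom surface is not below top surface")
  list(bottom = bot, top = top)
}

# surface fit with iterated MAD-based outlier rejection (columns crossing
# particles/contamination, or non-adsorbed particles mixed into a layer,
# give gross errors that a plain least-squares fit would absorb)
.robustSurfaceFit <- function(pts, side, order = 2L, locator = "gradient",
                              maxIter = 5L) {
  pts <- as.matrix(pts)
  s <- fitSurface(pts, order = order, side = side, locator = locator)
  for (it in seq_len(maxIter)) {
    res <- pts[, 3] - surfaceHeight(s, pts[, 1], pts[, 2])
    scale <- stats::mad(res)
    if (scale < 1e-9) scale <- sqrt(mean(res^2))
    keep <- abs(res - stats::median(res)) <= 3 * max(scale, 1e-9)
    need <- if (order == 2L) 5L else 4L
    if (all(keep) || sum(keep) < max(need, ceiling(0.5 * nrow(pts)))) break
    pts <- pts[keep, , drop = FALSE]
    s <- fitSurface(pts, order = order, side = side, locator = locator)
  }
  s
}

# Gaussian smoothing in x and y only (z untouched so boundaries stay put)
.lateralSmooth <- function(arr, sigmaVox) {
  d <- dim(arr)
  kx <- c(0:floor(d[1] / 2), -(ceiling(d[1] / 2) - 1):-1)[seq_len(d[1])] / d[1]
  ky <- c(0:floor(d[2] / 2), -(ceiling(d[2] / 2) - 1):-1)[seq_len(d[2])] / d[2]
  h <- exp(-2 * pi^2 * sigmaVox^2 * outer(kx^2, ky^2, "+"))
  out <- arr
  for (k in seq_len(d[3])) {
    out[, , k] <- Re(fft(fft(arr[, , k]) * h, inverse = TRUE)) / (d[1] * d[2])
  }
  out
}

.locateContamination <- function(vol, mask) {
  arr <- densities(vol)
  d <- dim(arr)
  vs <- voxelSizeNm(vol)
  prof <- zProfile(vol, mask)
  bounds <- .slabBounds(prof)
  if (is.null(bounds)) stop("no ice slab found to orient contamination against")
  thrDark <- .PHANTOM_ICE_DENSITY + 0.6 * .PHANTOM_CONTAM_DENSITY
  # dark voxels outside the slab = surface contamination candidates
  zIdx <- seq_len(d[3]) - 0.5
  outside <- zIdx < bounds[1] - 0.5 | zIdx > bounds[2] + 0.5
  cand <- array(FALSE, d)
  cand[, , outside] <- arr[, , outside] < thrDark
  comps <- .connectedComponents3d(cand)
  minVox <- max(4, round((4 / 3) * pi * (4 / vs)^3 / 8))
  comps <- comps[vapply(comps, nrow, integer(1)) >= minVox]
  if (length(comps) < 6)
    stop("need at least 3 contamination blobs per surface, found ",
         length(comps), " in total")
  mid <- mean(bounds) # voxel units
  anchB <- NULL; anchT <- NULL
  for (co in comps) {
    below <- mean(co[, 3]) < mid
    # face voxel nearest the vitreous ice, refined to the subvoxel
    # half-amplitude crossing of the blob along its anchor column
    k <- if (below) which.max(co[, 3]) else which.min(co[, 3])
    colP <- arr[co[k, 1], co[k, 2], ]
    # half level from this side of the slab only: the column may also
    # cross ice or a blob seated on the other surface
    zone <- if (below) seq_len(max(1, floor(bounds[1] + 1)))
            else seq(min(length(colP), ceiling(bounds[2] + 1)), length(colP))
    halfBlob <- 0.5 * min(colP[zone])
    cr <- .runCrossings(colP, halfBlob, refIdx = rep(co[k, 3], 2))
    zFace <- if (is.null(cr)) co[k, 3] - 0.5
             else if (below) cr[2] else cr[1]
    pt <- c((co[k, 1] - 0.5) * vs, (co[k, 2] - 0.5) * vs, zFace * vs)
    if (below) anchB <- rbind(anchB, pt) else anchT <- rbind(anchT, pt)
  }
  if (is.null(anchB) || nrow(anchB) < 3 || is.null(anchT) || nrow(anchT) < 3)
    stop("need at least 3 contamination blobs per surface (bottom: ",
         NROW(anchB), ", top: ", NROW(anchT), ")")
  fitAnchors <- function(pts, side) {
    ord <- if (nrow(pts) >= 10) 2L else 1L
    if (nrow(pts) >= 5)
      .robustSurfaceFit(pts, side = side, order = ord,
                        locator = "contamination")
    else fitSurface(pts, order = ord, side = side,
                    locator = "contamination")
  }
  bot <- fitAnchors(anchB, "bottom")
  top <- fitAnchors(anchT, "top")
  if (bot@c >= top@c) stop("bottom surface is not below top surface")
  list(bottom = bot, top = top)
}

.locateParticleLayer <- function(vol, hint, particleDiameter) {
  if (is.null(hint))
    stop("particle_layer strategy needs a layer-offset hint (nm)")
  det <- detectParticles(vol, diameterRange = particleDiameter)
  if (nrow(det) < 3) stop("fewer than 3 particles detected for layer fitting")
  bounds <- .slabBounds(zProfile(vol))
  if (is.null(bounds))
    stop("no density slab found to orient particle layers against")
  vsn <- voxelSizeNm(vol)
  zbG <- bounds[1] * vsn; ztG <- bounds[2] * vsn
  mkSurf <- function(sub, side) {
    s <- .robustSurfaceFit(sub[, c("x", "y", "z")], side = side,
                           order = if (nrow(sub) >= 12) 2L else 1L,
                           locator = "particle_layer")
    s@c <- s@c + if (side == "bottom") -hint else hint
    s
  }
  slabSurf <- function(side) {
    new("InterfaceSurface", side = side,
        c = if (side == "bottom") zbG else ztG,
        a = 0, b = 0, order = 1L, fitResidual = 0,
        locator = "gradient", supportPoints = 0L)
  }
  # assign each detection to the nearer slab bound; a side with too few
  # members, or a scattered "layer" whose fit residual exceeds a particle
  # diameter (non-adsorbed strays), falls back to the density bound
  nearBottom <- (det$z - zbG) <= (ztG - det$z)
  out <- list()
  for (side in c("bottom", "top")) {
    sub <- det[if (side == "bottom") nearBottom else !nearBottom, ,
               drop = FALSE]
    s <- if (nrow(sub) >= 3) mkSurf(sub, side) else NULL
    if (is.null(s) || s@fitResidual > particleDiameter) s <- slabSurf(side)
    out[[side]] <- s
  }
  if (out$bottom@c >= out$top@c)
    stop("bottom surface is not below top surface")
  out
}

#' Ice thickness, tilt and curvature statistics
#'
#' Evaluates both surfaces on an (x, y) grid, forms the thickness map
#' (clamped at zero where surfaces cross, flagged degenerate), extracts
#' minimum thickness over the centre disc (radius 20\% of the hole
#' radius) and over the edge annulus (centred ~100 nm inside the rim, or
#' at 80\% of the hole radius for holes smaller than ~125 nm), measures
#' each interface's tilt, and classifies curvature: per interface the mean
#' height over the centre disc is compared with the edge annulus; within
#' the 5 nm measurement error the interface is flat (C2), bulging away
#' from the ice is C1, recessed into the ice is C3, demoted to C4 when the
#' centre minimum thickness is below the particle minor axis.
#'
#' @param bottom,top \linkS4class{InterfaceSurface} objects.
#' @param holeRadius nm.
#' @param holeCenter numeric(2), nm; defaults to the surface radial centre.
#' @param particleMinorAxis nm, for the C3/C4 distinction.
#' @param gridStep nm, map resolution.
#' @param measurementError nm (default 5).
#' @return An \linkS4class{IceGeometry}.
#' @export
thicknessStats <- function(bottom, top, holeRadius,
                           holeCenter = c(bottom@x0, bottom@y0),
                           particleMinorAxis = 10, gridStep = 4,
                           measurementError = 5) {
  R <- holeRadius
  xs <- seq(holeCenter[1] - R, holeCenter[1] + R, by = gridStep)
  ys <- seq(holeCenter[2] - R, holeCenter[2] + R, by = gridStep)
  zb <- surfaceHeight(bottom, xs, ys, grid = TRUE)
  zt <- surfaceHeight(top, xs, ys, grid = TRUE)
  thick <- zt - zb
  r <- sqrt(outer((xs - holeCenter[1])^2, (ys - holeCenter[2])^2, "+"))
  holeMask <- r <= R
  # degeneracy means the surfaces cross inside the hole; extrapolated
  # quadratics may cross outside it without invalidating the measurement
  degen <- any(thick[holeMask] < 0)
  thick[thick < 0] <- 0
  centerMask <- r <= 0.2 * R
  edgeR <- if (R > 125) R - 100 else 0.8 * R
  edgeMask <- abs(r - edgeR) <= max(gridStep, 0.05 * R)
  tCenter <- min(thick[centerMask])
  tEdge <- min(thick[edgeMask])
  classify <- function(surf) {
    hC <- mean(surfaceHeight(surf, xs, ys, grid = TRUE)[centerMask])
    hE <- mean(surfaceHeight(surf, xs, ys, grid = TRUE)[edgeMask])
    outward <- if (surf@side == "bottom") hE - hC else hC - hE
    if (degen) return("C4")
    if (abs(outward) <= measurementError) "C2"
    else if (outward > 0) "C1"
    else if (tCenter < particleMinorAxis) "C4"
    else "C3"
  }
  new("IceGeometry",
      thicknessMap = thick, x = xs, y = ys, holeMask = holeMask,
      tCenterMin = tCenter, tEdgeMin = tEdge,
      curvatureBottom = classify(bottom), curvatureTop = classify(top),
      tiltBottom = surfaceTilt(bottom), tiltTop = surfaceTilt(top),
      measurementError = measurementError, degenerate = degen)
}
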