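# Particle detection and layer statistics: blob detection, assignment of
# centroids to interface layers by signed z distance, adsorbed fraction,
# layer tilt and saturation, projection overlap, behavior classification.

#' Detect particles by multi-scale blob detection
#'
#' Scale-normalized Laplacian-of-Gaussian detection for dark particles:
#' the volume is filtered at sigma = d / (2 sqrt(3)) for each candidate
#' diameter d, local response maxima above an adaptive threshold
#' (median + k * MAD of the response) are kept, and detections closer than
#' 0.7 diameters to a stronger one are suppressed.
#'
#' @param vol a \linkS4class{TomoVolume}.
#' @param diameterRange particle diameter(s) in nm, within 2-60; a scalar
#'   uses one scale, a length-2 range uses three log-spaced scales.
#' @param thresholdK MAD multiplier of the adaptive threshold.
#' @return data.frame(x, y, z (nm), score, diameter) sorted by score; may
#'   be empty.
#' @export
detectParticles <- function(vol, diameterRange = 10, thresholdK = 8) {
  if (any(diameterRange < 2) || any(diameterRange > 60))
    stop("diameterRange must lie within 2-60 nm")
  vs <- voxelSizeNm(vol)
  dVox <- min(diameterRange) / vs
  if (dVox < 2)
    stop("diameter below the Nyquist limit at this voxel size (",
         vs, " nm/voxel)")
  scales <- if (length(diameterRange) > 1 &&
                diff(range(diameterRange)) > 1e-9)
    exp(seq(log(min(diameterRange)), log(max(diameterRange)), length.out = 3))
  else min(diameterRange)
  arr <- densities(vol)
  det <- NULL
  for (dd in scales) {
    sigma <- dd / (2 * sqrt(3))
    resp <- .logResponse(arr, sigma, vs)
    # adaptive (noise-scaled) threshold with a floor relative to the
    # strongest response, so noiseless volumes do not admit ripple maxima
    thr <- max(stats::median(resp) + thresholdK * stats::mad(resp),
               0.25 * max(resp))
    mx <- .localMaxima3d(resp, thr)
    if (nrow(mx) == 0) next
    det <- rbind(det, data.frame(
      x = (mx[, 1] - 0.5) * vs, y = (mx[, 2] - 0.5) * vs,
      z = (mx[, 3] - 0.5) * vs,
      score = resp[mx], diameter = dd))
  }
  if (is.null(det))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      score = numeric(0), diameter = numeric(0)))
  det <- det[order(-det$score), ]
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    ki <- which(keep)
    d2 <- (det$x[ki] - det$x[i])^2 + (det$y[ki] - det$y[i])^2 +
          (det$z[ki] - det$z[i])^2
    minSep <- 0.7 * pmax(det$diameter[ki], det$diameter[i])
    keep[i] <- all(d2 >= minSep^2)
  }
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign particle centroids to interface layers
#'
#' Computes each particle's signed distance to the two surfaces measured
#' from the centre along z (positive = inside the ice); particles within
#' \code{cutoff} nm of a surface join that side's layer, the rest are
#' non-adsorbed (side "none"). Returns the particle table and a per-layer
#' summary (mean offset, plane tilt, count, saturation if an area is
#' given).
#'
#' @param centroids data.frame with x, y, z in nm (e.g. from
#'   \code{\link{detectParticles}}).
#' @param bottom,top \linkS4class{InterfaceSurface} objects.
#' @param cutoff adsorption cutoff, nm (default 10; layers sit 5-10 nm
#'   from the interface).
#' @param diameter particle diameter (nm) used for saturation.
#' @param holeArea area of the hole within the field, nm^2 (NA skips
#'   saturation).
#' @return list(particles = data.frame, layers = data.frame).
#' @export
assignToLayers <- function(centroids, bottom, top, cutoff = 10,
                           diameter = 10, holeArea = NA_real_) {
  stopifnot(cutoff > 0)
  p <- as.data.frame(centroids)
  zb <- surfaceHeight(bottom, p$x, p$y)
  zt <- surfaceHeight(top, p$x, p$y)
  if (any(zt < zb)) stop("surfaces cross within the particle extent")
  p$dBottom <- p$z - zb
  p$dTop <- zt - p$z
  nearB <- p$dBottom <= p$dTop
  p$adsorbed <- pmin(p$dBottom, p$dTop) <= cutoff
  p$side <- ifelse(!p$adsorbed, "none", ifelse(nearB, "bottom", "top"))
  p$layer <- ifelse(!p$adsorbed, NA_integer_, ifelse(nearB, 1L, 2L))
  layers <- NULL
  for (side in c("bottom", "top")) {
    sub <- p[p$side == side, , drop = FALSE]
    if (nrow(sub) == 0) next
    tilt <- if (nrow(sub) >= 3)
      tryCatch(layerTilt(sub), error = function(e) NA_real_)
    else NA_real_
    sat <- if (is.na(holeArea)) NA_real_
           else layerSaturation(nrow(sub), diameter, holeArea)
    layers <- rbind(layers, data.frame(
      layer = if (side == "bottom") 1L else 2L, side = side,
      meanOffset = mean(if (side == "bottom") sub$dBottom else sub$dTop),
      tilt = tilt, count = nrow(sub), saturation = sat,
      behavior = "unknown"))
  }
  if (is.null(layers))
    layers <- data.frame(layer = integer(0), side = character(0),
                         meanOffset = numeric(0), tilt = numeric(0),
                         count = integer(0), saturation = numeric(0),
                         behavior = character(0))
  list(particles = p, layers = layers)
}

#' Layer-count token for a field of view
#'
#' Expresses the layer situation in the survey-table vocabulary: "0", "1"
#' or "2" populated layers, "1-2" when sub-regions of one field disagree,
#' with "+" appended when the non-adsorbed count exceeds 5\% of the
#' layered count.
#'
#' @param particles particle table from \code{\link{assignToLayers}}.
#' @param regions optional factor splitting particles into sub-regions.
#' @return character token.
#' @export
layerCountToken <- function(particles, regions = NULL) {
  countIn <- function(sub) length(unique(stats::na.omit(sub$layer)))
  if (is.null(regions)) {
    n <- countIn(particles)
  } else {
    per <- vapply(split(particles, regions), countIn, integer(1))
    n <- if (length(unique(per)) > 1)
      paste0(min(per), "-", max(per)) else per[1]
  }
  nAds <- sum(particles$adsorbed)
  nFree <- sum(!particles$adsorbed)
  tok <- as.character(n)
  if (nAds > 0 && nFree > 0.05 * nAds) tok <- paste0(tok, "+")
  tok
}

#' Fraction of particles adsorbed to an interface
#'
#' @param particles particle table with an \code{adsorbed} column.
#' @return count(adsorbed) / count(all).
#' @export
adsorbedFraction <- function(particles) {
  if (nrow(particles) == 0) stop("empty particle list")
  sum(particles$adsorbed) / nrow(particles)
}

#' Tilt of a particle layer
#'
#' Fits a plane through the layer centroids and returns the absolute angle
#' between its normal and the beam axis (degrees).
#'
#' @param layerParticles data.frame with x, y, z (>= 3 non-collinear).
#' @return degrees in [0, 90).
#' @export
layerTilt <- function(layerParticles) {
  surfaceTilt(fitSurface(layerParticles[, c("x", "y", "z")], order = 1L,
                         locator = "particle_layer"))
}

#' Layer saturation
#'
#' Percent of the achievable packing occupied:
#' \code{100 * count * footprint / (area * 0.9069)} with the hexagonal
#' packing limit 0.9069, capped at 100.
#'
#' @param count particles in the layer.
#' @param diameter footprint diameter, nm.
#' @param area layer area within the field, nm^2.
#' @return percent in [0, 100].
#' @export
layerSaturation <- function(count, diameter, area) {
  if (area <= 0) stop("zero or negative layer area")
  min(100, 100 * count * pi * (diameter / 2)^2 / (area * .HEX_PACKING))
}

#' Particle overlap in the projection direction
#'
#' Projects particle centres along z; a particle overlaps when any other
#' centre lies within one diameter in (x, y). Uniquely identifiable
#' particles are the non-overlapping ones. Neighbour search uses lateral
#' cell binning at the particle diameter.
#'
#' @param particles data.frame with x, y (nm).
#' @param diameter nm.
#' @return list(overlapFraction, uniqueCount, overlapped = logical vector).
#' @export
projectionOverlap <- function(particles, diameter) {
  stopifnot(diameter > 0)
  n <- nrow(particles)
  if (n == 0)
    return(list(overlapFraction = NA_real_, uniqueCount = 0L,
                overlapped = logical(0)))
  cellX <- floor(particles$x / diameter)
  cellY <- floor(particles$y / diameter)
  key <- paste(cellX, cellY)
  lut <- split(seq_len(n), key)
  overlapped <- logical(n)
  for (i in seq_len(n)) {
    if (overlapped[i]) next
    nbr <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cellX[i] + dx, cellY[i] + dy)
      nbr <- c(nbr, lut[[k]])
    }
    nbr <- nbr[nbr != i]
    if (!length(nbr)) next
    d2 <- (particles$x[nbr] - particles$x[i])^2 +
          (particles$y[nbr] - particles$y[i])^2
    hit <- nbr[d2 < diameter^2]
    if (length(hit)) { overlapped[i] <- TRUE; overlapped[hit] <- TRUE }
  }
  list(overlapFraction = mean(overlapped),
       uniqueCount = sum(!overlapped), overlapped = overlapped)
}

#' Classify bulk particle behavior in a region
#'
#' B1 non-adsorbed; B2 adsorbed without preferred orientation; B3 adsorbed
#' with preferred orientation(s); B4/B5 (partial/denatured particles) are
#' only assignable from ground-truth or manual fragment annotation, since
#' denatured protein is not distinguishable from clean interfaces in the
#' densities. B2/B3 calls need at least 5 particles, otherwise "unknown".
#'
#' @param adsorbed logical: is the layer at an interface?
#' @param orientation an \linkS4class{OrientationStats} or NULL.
#' @param n particle count in the layer.
#' @param fragmentsAnnotation optional manual code "B4" or "B5".
#' @return a B-code string.
#' @export
classifyBehavior <- function(adsorbed, orientation = NULL, n = NA_integer_,
                             fragmentsAnnotation = NULL) {
  if (!is.null(fragmentsAnnotation)) {
    stopifnot(fragmentsAnnotation %in% c("B4", "B5"))
    return(fragmentsAnnotation)
  }
  if (!adsorbed) return("B1")
  if (is.null(orientation) || is.na(n) || n < 5) return("unknown")
  multiMode <- orientation@modeCount >= 2L &&
    sum(sort(orientation@weights, decreasing = TRUE)[1:2]) >= 0.8
  if (orientation@dispersionClass == "none" && !multiMode) "B2" else "B3"
}
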