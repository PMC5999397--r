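# Collection-strategy advisor: turns a measured hole characterization into
# one of four actions, mirroring how screening tomography informs
# single-particle collection.

#' Recommend a single-particle collection strategy
#'
#' Rule cascade over a completed characterization:
#' \enumerate{
#'   \item If a radial band exists where the ice is thin enough for only a
#'     single particle layer (thickness <= particle diameter + 2 x
#'     \code{clearance}, the particle plus 10-20 nm of space to each
#'     interface; clearance defaults to 20 nm), collect at a distance d
#'     from the hole edge: d = hole radius minus the outer radius of that
#'     band.
#'   \item Else, with a single populated layer but strong apparent
#'     preferred orientation, collect with intentional stage tilts; the
#'     tilt set is chosen greedily from candidate angles to maximize
#'     projection-orientation coverage of the detected modes.
#'   \item Else (double layers and/or thick ice throughout) collect with
#'     caveats, carrying the bilayer midway-defocus CTF limit - or reject
#'     when the ice exceeds \code{thickCeiling} (default 100 nm)
#'     everywhere and layer saturations are low.
#' }
#' Incomplete characterizations give action "indeterminate" naming the
#' missing inputs.
#'
#' @param geometry an \linkS4class{IceGeometry}.
#' @param layers layer table (from \code{\link{assignToLayers}}).
#' @param orientation an \linkS4class{OrientationStats} or NULL.
#' @param particleDiameter nm.
#' @param holeRadius nm; defaults to the geometry map extent.
#' @param clearance nm of space between the particle and each interface.
#' @param thickCeiling nm; near-ideal ice ceiling.
#' @param kv voltage for the attached CTF limits.
#' @return A \linkS4class{Recommendation}.
#' @export
recommendStrategy <- function(geometry, layers, orientation,
                              particleDiameter, holeRadius = NULL,
                              clearance = 20, thickCeiling = 100, kv = 300) {
  missing <- c(
    if (is.null(geometry)) "geometry",
    if (is.null(layers)) "layers",
    if (is.null(particleDiameter) || is.na(particleDiameter)) "particleDiameter")
  if (length(missing))
    return(new("Recommendation", action = "indeterminate",
               offsetD = NA_real_, tiltAngles = numeric(0),
               rationale = paste("missing input:", missing),
               expectedLimits = list()))
  xs <- geometry@x; ys <- geometry@y
  cx <- mean(range(xs)); cy <- mean(range(ys))
  r <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))
  if (is.null(holeRadius)) holeRadius <- max(r[geometry@holeMask])
  thr <- particleDiameter + 2 * clearance
  inHole <- geometry@holeMask
  thin <- inHole & geometry@thicknessMap <= thr & geometry@thicknessMap > 0
  nLayers <- sum(layers$count > 0)
  rationale <- character(0)
  if (any(thin)) {
    rOuter <- max(r[thin])
    d <- max(holeRadius - rOuter, 1)
    rationale <- c(rationale,
      sprintf("ice <= %.0f nm (particle %.0f nm + 2 x %.0f nm clearance) within %.0f nm of the hole centre: only a single layer fits there",
              thr, particleDiameter, clearance, rOuter))
    return(new("Recommendation", action = "collect_at_offset", offsetD = d,
               tiltAngles = numeric(0), rationale = rationale,
               expectedLimits = list()))
  }
  strongOrient <- !is.null(orientation) &&
    orientation@dispersionClass == "strong"
  if (nLayers <= 1 && strongOrient) {
    tilts <- .chooseTilts(orientation)
    rationale <- c(rationale,
      "single particle layer with strong apparent preferred orientation",
      sprintf("tilted collection at {%s} degrees expands orientation coverage",
              paste(tilts, collapse = ", ")))
    return(new("Recommendation", action = "tilted_collection",
               offsetD = NA_real_, tiltAngles = tilts,
               rationale = rationale, expectedLimits = list()))
  }
  # bilayer / thick-ice territory
  tRep <- stats::median(geometry@thicknessMap[inHole])
  dzA <- bilayerDefocusOffset(tRep) * 10  # nm -> Angstrom
  lim <- defocusErrorResolutionLimit(dzA, kv = kv)
  limits <- list(bilayerMidwayLimitA = as.numeric(lim),
                 bilayerOffsetNm = bilayerDefocusOffset(tRep))
  sats <- layers$saturation[!is.na(layers$saturation)]
  lowSat <- length(sats) > 0 && all(sats < 50)
  allThick <- min(geometry@thicknessMap[inHole]) > thickCeiling
  if (allThick && lowSat) {
    rationale <- c(rationale,
      sprintf("ice exceeds %.0f nm everywhere and layer saturations are low: collection would be inefficient",
              thickCeiling))
    return(new("Recommendation", action = "reject", offsetD = NA_real_,
               tiltAngles = numeric(0), rationale = rationale,
               expectedLimits = limits))
  }
  rationale <- c(rationale,
    sprintf("two layers and/or >%.0f nm-thick ice throughout; whole-image defocus lands midway between layers",
            min(thickCeiling, tRep)),
    sprintf("expected CTF limit ~%.1f A from a %.0f nm layer separation",
            as.numeric(lim), tRep))
  new("Recommendation", action = "collect_with_caveats", offsetD = NA_real_,
      tiltAngles = numeric(0), rationale = rationale,
      expectedLimits = limits)
}

# greedy tilt-set choice maximizing coverage of the detected modes
.chooseTilts <- function(orientation, candidates = c(10, 20, 30, 40),
                         maxTilts = 2L, bandwidth = 10) {
  modes <- orientation@modes
  tilts <- 0
  for (i in seq_len(maxTilts)) {
    gains <- vapply(candidates, function(a) {
      tiltExpandedCoverage(modes, 1L, c(tilts, a), bandwidth, nGrid = 4000L)
    }, numeric(1))
    best <- which.max(gains)
    if (gains[best] <= tiltExpandedCoverage(modes, 1L, tilts, bandwidth,
                                            nGrid = 4000L) + 1e-9) break
    tilts <- c(tilts, candidates[best])
    candidates <- candidates[-best]
  }
  sort(unique(tilts))
}
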