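# End-to-end profiling: volume -> interfaces -> ice geometry -> particles
# -> layers -> orientation/overlap -> taxonomy -> recommendation, collected
# into a ProfileReport that serializes to JSON.

#' Run the full grid-hole profiling pipeline
#'
#' Locates the interfaces, measures ice geometry, detects particles,
#' assigns them to layers, computes adsorption/overlap statistics,
#' optionally folds in per-particle orientation annotations (orientations
#' are not estimated from densities), and attaches a collection
#' recommendation. Stages that fail are recorded as
#' "indeterminate: <reason>" in the report rather than aborting it.
#'
#' @param vol a \linkS4class{TomoVolume} (or MRC path).
#' @param particleDiameter nm.
#' @param holeRadius nm (for masks and saturation); NULL uses 45\% of the
#'   smaller lateral field extent.
#' @param cutoff adsorption cutoff, nm.
#' @param strategy interface locator strategy.
#' @param hint layer-offset hint for the particle_layer strategy, nm.
#' @param orientations optional n x 3 matrix of particle orientation axes
#'   aligned with the detected particle order, or a CSV path with
#'   vx, vy, vz columns.
#' @param bin binning factor applied before analysis.
#' @param seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return A \linkS4class{ProfileReport}.
#' @export
runPipeline <- function(vol, particleDiameter = 10, holeRadius = NULL,
                        cutoff = 10, strategy = "gradient", hint = NULL,
                        orientations = NULL, bin = 1L, seed = NA_integer_) {
  if (is.character(vol)) vol <- readMRC(vol)
  if (bin > 1L) vol <- binVolume(vol, bin)
  d <- dim(vol)
  vs <- voxelSizeNm(vol)
  if (is.null(holeRadius)) holeRadius <- 0.45 * min(d[1], d[2]) * vs
  status <- list()
  emptyParticles <- data.frame(x = numeric(0), y = numeric(0),
                               z = numeric(0), score = numeric(0),
                               diameter = numeric(0))
  emptyLayers <- data.frame(layer = integer(0), side = character(0),
                            meanOffset = numeric(0), tilt = numeric(0),
                            count = integer(0), saturation = numeric(0),
                            behavior = character(0))

  xs <- .axisCoords(d[1], vs); ys <- .axisCoords(d[2], vs)
  holeMask <- sqrt(outer((xs - d[1] * vs / 2)^2,
                         (ys - d[2] * vs / 2)^2, "+")) <= holeRadius
  surfaces <- tryCatch(
    locateInterfaces(vol, strategy, hint = hint, mask = holeMask,
                     particleDiameter = particleDiameter),
    error = function(e) e)
  geom <- NULL
  if (inherits(surfaces, "error")) {
    status$geometry <- paste("indeterminate:", conditionMessage(surfaces))
    surfaces <- NULL
  } else {
    geom <- thicknessStats(surfaces$bottom, surfaces$top, holeRadius,
                           holeCenter = c(d[1], d[2]) * vs / 2,
                           particleMinorAxis = particleDiameter)
    status$geometry <- "ok"
  }

  det <- tryCatch(detectParticles(vol, particleDiameter),
                  error = function(e) e)
  if (inherits(det, "error")) {
    status$particles <- paste("indeterminate:", conditionMessage(det))
    det <- emptyParticles
  } else status$particles <- "ok"

  particles <- det
  layers <- emptyLayers
  adsorbed <- NA_real_
  if (!is.null(surfaces) && nrow(det) > 0) {
    asg <- assignToLayers(det, surfaces$bottom, surfaces$top,
                          cutoff = cutoff, diameter = particleDiameter,
                          holeArea = pi * holeRadius^2)
    particles <- asg$particles
    layers <- asg$layers
    adsorbed <- adsorbedFraction(particles)
    status$layers <- "ok"
  } else {
    status$layers <- "indeterminate: needs surfaces and detections"
  }

  orient <- NULL
  if (!is.null(orientations) && nrow(particles) > 0) {
    if (is.character(orientations)) {
      tb <- utils::read.csv(orientations)
      orientations <- as.matrix(tb[, c("vx", "vy", "vz")])
    }
    ads <- isTRUE2(particles$adsorbed)
    vsel <- orientations[seq_len(min(nrow(orientations), nrow(particles))), ,
                         drop = FALSE]
    if (any(ads) && nrow(orientations) == nrow(particles))
      vsel <- orientations[ads, , drop = FALSE]
    orient <- tryCatch(orientationDispersion(.unitRows(vsel)),
                       error = function(e) NULL)
  }

  overlap <- if (nrow(particles) > 0)
    projectionOverlap(particles, particleDiameter)
  else list(overlapFraction = NA_real_, uniqueCount = 0L,
            overlapped = logical(0))

  if (nrow(layers) > 0) {
    for (i in seq_len(nrow(layers))) {
      layers$behavior[i] <- classifyBehavior(TRUE, orient, layers$count[i])
    }
  }
  taxonomy <- list(
    curvature = if (!is.null(geom))
      c(bottom = geom@curvatureBottom, top = geom@curvatureTop) else NULL,
    behavior = unique(c(
      if (any(!isTRUE2(particles$adsorbed))) "B1",
      layers$behavior[layers$behavior != "unknown"])))

  rec <- if (!is.null(geom))
    recommendStrategy(geom, layers, orient, particleDiameter,
                      holeRadius = holeRadius)
  else new("Recommendation", action = "indeterminate", offsetD = NA_real_,
           tiltAngles = numeric(0), rationale = "missing input: geometry",
           expectedLimits = list())

  new("ProfileReport",
      meta = list(shape = dim(vol), voxelSize = voxelSize(vol),
                  version = as.character(utils::packageVersion("iceProfiler")),
                  seed = seed, timestamp = format(Sys.time(), tz = "UTC")),
      geometry = geom, particles = particles, layers = layers,
      orientation = orient,
      stats = list(adsorbedFraction = adsorbed,
                   overlap = overlap[c("overlapFraction", "uniqueCount")],
                   taxonomy = taxonomy, status = status),
      recommendation = rec)
}

#' Serialize a ProfileReport to JSON
#'
#' Numeric fields carry explicit unit-suffixed names (nm, degrees,
#' percent, ångström). Timestamps are excluded from determinism: reruns
#' with the same seed differ only there.
#'
#' @param report a \linkS4class{ProfileReport}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProfileReport <- function(report, path) {
  g <- report@geometry
  rec <- report@recommendation
  obj <- list(
    meta = report@meta,
    geometry = if (is.null(g)) NULL else list(
      t_center_min_nm = g@tCenterMin, t_edge_min_nm = g@tEdgeMin,
      curvature_bottom = g@curvatureBottom, curvature_top = g@curvatureTop,
      tilt_bottom_deg = g@tiltBottom, tilt_top_deg = g@tiltTop,
      measurement_error_nm = g@measurementError, degenerate = g@degenerate),
    particles_n = nrow(report@particles),
    adsorbed_fraction = report@stats$adsorbedFraction,
    layers = report@layers,
    orientation = if (is.null(report@orientation)) NULL else list(
      n = report@orientation@n, R = report@orientation@R,
      mode_count = report@orientation@modeCount,
      class = report@orientation@dispersionClass),
    overlap = report@stats$overlap,
    taxonomy = report@stats$taxonomy,
    status = report@stats$status,
    recommendation = if (is.null(rec)) NULL else list(
      action = rec@action, offset_d_nm = rec@offsetD,
      tilt_angles_deg = rec@tiltAngles, rationale = rec@rationale,
      expected_limits = rec@expectedLimits))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
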