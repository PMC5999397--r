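#' @rdname accessors
#' @aliases densities,TomoVolume-method
setMethod("densities", "TomoVolume", function(object) object@data)

#' @rdname accessors
#' @aliases voxelSize,TomoVolume-method
setMethod("voxelSize", "TomoVolume", function(object) object@voxelSize)

#' @rdname accessors
#' @aliases voxelSizeNm,TomoVolume-method
setMethod("voxelSizeNm", "TomoVolume", function(object) object@voxelSize / 10)

#' @describeIn accessors dimensions of the density array (voxels).
#' @export
setMethod("dim", "TomoVolume", function(x) dim(x@data))

#' @rdname accessors
#' @aliases surfaceHeight,InterfaceSurface-method
setMethod("surfaceHeight", "InterfaceSurface",
  function(surface, x, y, grid = FALSE) {
    if (grid) {
      base <- outer(surface@a * x, surface@b * y, "+") + surface@c
      if (surface@order == 2L && surface@q != 0)
        base <- base + surface@q *
          outer((x - surface@x0)^2, (y - surface@y0)^2, "+")
      base
    } else {
      z <- surface@a * x + surface@b * y + surface@c
      if (surface@order == 2L && surface@q != 0)
        z <- z + surface@q * ((x - surface@x0)^2 + (y - surface@y0)^2)
      z
    }
  })

setMethod("show", "TomoVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("TomoVolume: %d x %d x %d voxels at %.2f A/voxel (%.0f x %.0f x %.0f nm)\n",
              d[1], d[2], d[3], object@voxelSize,
              d[1] * object@voxelSize / 10, d[2] * object@voxelSize / 10,
              d[3] * object@voxelSize / 10))
  cat(sprintf("  density range [%.3g, %.3g], mean %.3g\n",
              min(object@data), max(object@data), mean(object@data)))
})

setMethod("show", "InterfaceSurface", function(object) {
  cat(sprintf("InterfaceSurface (%s, locator=%s): z = %.4f x + %.4f y + %.2f",
              object@side, object@locator, object@a, object@b, object@c))
  if (object@order == 2L)
    cat(sprintf(" + %.3g r^2 about (%.0f, %.0f)", object@q, object@x0, object@y0))
  cat(sprintf("\n  tilt %.2f deg, residual %.2f nm RMS, %d support points\n",
              surfaceTilt(object), object@fitResidual, object@supportPoints))
})

setMethod("show", "IceGeometry", function(object) {
  cat(sprintf("IceGeometry: t_center_min %.1f nm, t_edge_min %.1f nm (+/- %.0f nm)\n",
              object@tCenterMin, object@tEdgeMin, object@measurementError))
  cat(sprintf("  curvature %s/%s (bottom/top), tilt %.1f/%.1f deg%s\n",
              object@curvatureBottom, object@curvatureTop,
              object@tiltBottom, object@tiltTop,
              if (object@degenerate) " [degenerate: surfaces cross]" else ""))
})

setMethod("show", "OrientationStats", function(object) {
  cat(sprintf("OrientationStats: n=%d, R=%.3f%s, %d mode(s), class '%s'\n",
              object@n, object@R, if (object@axial) " (axial)" else "",
              object@modeCount, object@dispersionClass))
})

setMethod("show", "Recommendation", function(object) {
  cat(sprintf("Recommendation: %s\n", object@action))
  if (!is.na(object@offsetD))
    cat(sprintf("  collect %.0f nm from the hole edge\n", object@offsetD))
  if (length(object@tiltAngles))
    cat(sprintf("  stage tilts: %s deg\n",
                paste(object@tiltAngles, collapse = ", ")))
  for (r in object@rationale) cat("  - ", r, "\n", sep = "")
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d particles (%.0f%% adsorbed), seed %d\n",
              nrow(object@particles), 100 * object@realizedAdsorbedFraction,
              object@seed))
})

setMethod("show", "ProfileReport", function(object) {
  cat("ProfileReport\n")
  cat("  volume:", paste(unlist(object@meta$shape), collapse = "x"),
      "voxels at", object@meta$voxelSize, "A\n")
  if (!is.null(object@geometry)) show(object@geometry)
  cat(sprintf("  %d particles in %d layer(s); adsorbed fraction %s\n",
              nrow(object@particles), nrow(object@layers),
              format(object@stats$adsorbedFraction, digits = 3)))
})

#' Extract per-particle or per-layer tables from a report
#'
#' @param report a \linkS4class{ProfileReport}.
#' @return \code{particleTable} returns the particle data.frame (centres in
#'   nm, signed interface distances, layer membership);
#'   \code{layerTable} the per-layer summary (offset, tilt, count,
#'   saturation, behavior code).
#' @export
particleTable <- function(report) report@particles

#' @rdname particleTable
#' @export
layerTable <- function(report) report@layers
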