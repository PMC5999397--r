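#' @import methods
NULL

#' TomoVolume: a 3D tomographic density volume
#'
#' Container for a reconstructed tomogram (or synthetic phantom). The array
#' is indexed \code{[x, y, z]} with z along the electron beam; densities
#' follow cryoEM convention (protein/ice darker, i.e. more negative, than
#' the vacuum background). Voxel size is carried in ångström as in the
#' MRC2014 header; all analysis functions report lengths in nanometres,
#' converting only at this boundary. Voxel centres sit at
#' \code{(index - 0.5) * voxelSize} (0-based index + 0.5 convention).
#'
#' @slot data numeric 3D array of densities.
#' @slot voxelSize numeric(1), voxel edge length in ångström.
#' @exportClass TomoVolume
setClass("TomoVolume",
  representation(data = "array", voxelSize = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
        object@voxelSize <= 0) return("voxelSize must be a positive scalar (Angstrom)")
    TRUE
  })

#' Construct a TomoVolume
#'
#' @param data numeric 3D array, indexed \code{[x, y, z]}.
#' @param voxelSize voxel edge length in ångström.
#' @return A \linkS4class{TomoVolume}.
#' @examples
#' v <- TomoVolume(array(0, c(8, 8, 8)), voxelSize = 10)
#' dim(v)
#' @export
TomoVolume <- function(data, voxelSize) {
  new("TomoVolume", data = data, voxelSize = as.numeric(voxelSize))
}

#' InterfaceSurface: fitted model of one air-water interface
#'
#' The surface is modelled as a plane \code{z = a*x + b*y + c}, optionally
#' with a radially symmetric quadratic term \code{q * ((x-x0)^2 + (y-y0)^2)}
#' about the hole centre. All coefficients are in nm (slopes unitless).
#' \code{side} follows the lower-z = bottom convention of tomogram viewers.
#'
#' @slot side "bottom" or "top" (bottom = lower z).
#' @slot a,b,c plane coefficients, nm.
#' @slot q quadratic radial coefficient (1/nm); 0 for order-1 fits.
#' @slot x0,y0 centre of the radial term, nm.
#' @slot order 1 (plane) or 2 (plane + radial quadratic).
#' @slot fitResidual RMS misfit in z, nm.
#' @slot locator how the surface was located: "gradient", "contamination",
#'   "particle_layer" or "analytic" (phantom ground truth).
#' @slot supportPoints number of points supporting the fit.
#' @exportClass InterfaceSurface
setClass("InterfaceSurface",
  representation(side = "character", a = "numeric", b = "numeric",
                 c = "numeric", q = "numeric", x0 = "numeric", y0 = "numeric",
                 order = "integer", fitResidual = "numeric",
                 locator = "character", supportPoints = "integer"),
  prototype(q = 0, x0 = 0, y0 = 0, order = 1L, fitResidual = 0,
            locator = "analytic", supportPoints = 0L),
  validity = function(object) {
    if (!object@side %in% c("bottom", "top")) return("side must be bottom|top")
    if (object@fitResidual < 0) return("fitResidual must be >= 0")
    if (!object@order %in% c(1L, 2L)) return("order must be 1 or 2")
    TRUE
  })

#' IceGeometry: thickness, tilt and curvature of the ice in a hole
#'
#' Curvature codes follow the standard grid-hole taxonomy: C1 convex
#' (interface bulging away from the ice), C2 flat, C3 concave with centre
#' thicker than the particle minor axis, C4 concave with centre thinner
#' than the particle minor axis.
#'
#' @slot thicknessMap matrix of ice thickness (nm) on the (x, y) grid.
#' @slot x,y grid coordinates (nm) of the map rows/columns.
#' @slot holeMask logical matrix, TRUE inside the hole.
#' @slot tCenterMin minimum thickness (nm) over the centre disc
#'   (radius 20\% of the hole radius).
#' @slot tEdgeMin minimum thickness (nm) over the edge annulus
#'   (centred ~100 nm inside the hole rim).
#' @slot curvatureBottom,curvatureTop C1|C2|C3|C4.
#' @slot tiltBottom,tiltTop interface tilt from the beam axis, degrees.
#' @slot measurementError per-measurement error, nm (default 5).
#' @slot degenerate TRUE when the surfaces cross (thickness clamped to 0).
#' @exportClass IceGeometry
setClass("IceGeometry",
  representation(thicknessMap = "matrix", x = "numeric", y = "numeric",
                 holeMask = "matrix", tCenterMin = "numeric",
                 tEdgeMin = "numeric", curvatureBottom = "character",
                 curvatureTop = "character", tiltBottom = "numeric",
                 tiltTop = "numeric", measurementError = "numeric",
                 degenerate = "logical"),
  prototype(measurementError = 5, degenerate = FALSE),
  validity = function(object) {
    if (any(object@thicknessMap < 0, na.rm = TRUE))
      return("thicknessMap must be non-negative")
    ok <- c("C1", "C2", "C3", "C4")
    if (!object@curvatureBottom %in% ok || !object@curvatureTop %in% ok)
      return("curvature codes must be C1..C4")
    if (object@tiltBottom < 0 || object@tiltBottom >= 90 ||
        object@tiltTop < 0 || object@tiltTop >= 90)
      return("tilt must lie in [0, 90) degrees")
    TRUE
  })

#' PhantomConfig: generative description of a synthetic grid hole
#'
#' Full parameterization of a synthetic grid-hole tomogram: two bounding
#' air-water interfaces (radial quadratic profiles plus a rigid plane
#' tilt), particle layers adsorbed at a fixed offset from each interface,
#' free mid-ice particles, surface contamination, interface protein-debris
#' fragments, Gaussian noise and an optional missing-wedge filter.
#' Construct with \code{\link{phantomConfig}}, which supplies defaults.
#'
#' @slot volumeShape integer(3), voxels per (x, y, z) axis.
#' @slot voxelSize ångström per voxel.
#' @slot holeRadius hole radius, nm.
#' @slot bottomProfile,topProfile list(class, center, edge): curvature class
#'   C1..C4 and interface offsets from the mid-plane (nm) at the hole
#'   centre and edge, so local thickness = bottom offset + top offset.
#' @slot interfaceTilt plane tilt (degrees, about y) added to both surfaces.
#' @slot particleDiameter particle minor axis, nm.
#' @slot aspectRatio long-axis / minor-axis of the soft ellipsoid particles.
#' @slot nParticles total particle count (adsorbed + non-adsorbed).
#' @slot adsorbedFraction fraction of nParticles placed in interface layers.
#' @slot layerOffset particle-centre distance from the interface, nm (0-10).
#' @slot layerSplit fraction of adsorbed particles on the bottom interface.
#' @slot orientationModel list(type = "uniform") or list(type = "modes",
#'   directions = 3-column matrix, kappa, weights).
#' @slot saturationCap maximum realized per-layer saturation, percent.
#' @slot nFreeParticles extra non-adsorbed particles mid-ice.
#' @slot contaminationDensity surface contamination blobs per µm² per surface.
#' @slot fragmentDensity small debris blobs per µm² at each interface.
#' @slot noiseSigma Gaussian noise standard deviation, density units.
#' @slot missingWedge logical; apply the missing-wedge Fourier filter.
#' @slot wedgeTiltRange retained tilt half-range, degrees (tilt axis = x).
#' @slot seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(volumeShape = "integer", voxelSize = "numeric",
                 holeRadius = "numeric", bottomProfile = "list",
                 topProfile = "list", interfaceTilt = "numeric",
                 particleDiameter = "numeric", aspectRatio = "numeric",
                 nParticles = "integer", adsorbedFraction = "numeric",
                 layerOffset = "numeric", layerSplit = "numeric",
                 orientationModel = "list", saturationCap = "numeric",
                 nFreeParticles = "integer", contaminationDensity = "numeric",
                 fragmentDensity = "numeric", noiseSigma = "numeric",
                 missingWedge = "logical", wedgeTiltRange = "numeric",
                 seed = "integer"))

#' GroundTruth: truth sidecar for a synthetic phantom
#'
#' @slot particles data.frame with one row per particle: x, y, z (nm),
#'   vx, vy, vz (orientation unit vector), adsorbed, side
#'   ("bottom"|"top"|"none"), layer (integer or NA), diameter (nm).
#' @slot surfaces list(bottom, top) of analytic surface descriptions
#'   (z0, centerOffset, edgeOffset, holeRadius, slopeX, slopeY, cx, cy).
#' @slot thicknessMap matrix (nm) on the volume (x, y) grid.
#' @slot x,y grid coordinates, nm.
#' @slot taxonomy list of region codes (interface A codes, behavior B codes,
#'   curvature C codes).
#' @slot realizedAdsorbedFraction realized adsorbed fraction of nParticles.
#' @slot realizedSaturation named numeric, percent per layer.
#' @slot config the generating \linkS4class{PhantomConfig}.
#' @slot seed integer seed used.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(particles = "data.frame", surfaces = "list",
                 thicknessMap = "matrix", x = "numeric", y = "numeric",
                 taxonomy = "list", realizedAdsorbedFraction = "numeric",
                 realizedSaturation = "numeric", config = "PhantomConfig",
                 seed = "integer"))

#' OrientationStats: preferred-orientation summary of a particle layer
#'
#' @slot n number of orientation vectors.
#' @slot R mean resultant length in [0, 1] (axial variant when sign
#'   ambiguous).
#' @slot axial logical; whether axial statistics were used.
#' @slot modeCount number of orientation clusters.
#' @slot modes 3-column matrix of cluster mean directions.
#' @slot weights cluster weights, summing to 1.
#' @slot dispersionClass "none", "some" or "strong".
#' @exportClass OrientationStats
setClass("OrientationStats",
  representation(n = "integer", R = "numeric", axial = "logical",
                 modeCount = "integer", modes = "matrix",
                 weights = "numeric", dispersionClass = "character"),
  validity = function(object) {
    if (object@R < -1e-9 || object@R > 1 + 1e-9) return("R must lie in [0,1]")
    if (object@n >= 1L && object@modeCount < 1L)
      return("modeCount must be >= 1 when n >= 1")
    if (length(object@weights) && abs(sum(object@weights) - 1) > 1e-6)
      return("weights must sum to 1")
    TRUE
  })

#' Recommendation: collection-strategy advice for a characterized hole
#'
#' @slot action one of "collect_at_offset", "tilted_collection",
#'   "collect_with_caveats", "reject", "indeterminate".
#' @slot offsetD distance d from the hole edge at which to collect, nm
#'   (collect_at_offset only, NA otherwise).
#' @slot tiltAngles stage tilt angles alpha, degrees (tilted_collection).
#' @slot rationale character vector of triggered rules (nonempty).
#' @slot expectedLimits list of CTF resolution bounds attached to the
#'   recommendation (e.g. bilayer midway-defocus limit).
#' @exportClass Recommendation
setClass("Recommendation",
  representation(action = "character", offsetD = "numeric",
                 tiltAngles = "numeric", rationale = "character",
                 expectedLimits = "list"),
  validity = function(object) {
    if (!object@action %in% c("collect_at_offset", "tilted_collection",
                              "collect_with_caveats", "reject",
                              "indeterminate"))
      return("unknown action")
    if (length(object@rationale) == 0L) return("rationale must be nonempty")
    if (object@action == "collect_at_offset" &&
        (is.na(object@offsetD) || object@offsetD <= 0))
      return("offsetD must be > 0 for collect_at_offset")
    TRUE
  })

#' ProfileReport: full characterization of one tomogram
#'
#' Aggregates the output of the simulate/profile pipeline: volume metadata,
#' ice geometry, particle and layer tables, orientation and overlap
#' statistics, taxonomy codes and the collection recommendation.
#'
#' @slot meta list: path, voxel size, shape, tool version, seed, timestamp.
#' @slot geometry an \linkS4class{IceGeometry} or NULL.
#' @slot particles particle table (data.frame).
#' @slot layers layer table (data.frame).
#' @slot orientation an \linkS4class{OrientationStats} or NULL.
#' @slot stats list: adsorbed fraction, overlap stats, taxonomy codes,
#'   per-stage status ("ok" or "indeterminate: <reason>").
#' @slot recommendation a \linkS4class{Recommendation} or NULL.
#' @exportClass ProfileReport
setClass("ProfileReport",
  representation(meta = "list", geometry = "ANY", particles = "data.frame",
                 layers = "data.frame", orientation = "ANY", stats = "list",
                 recommendation = "ANY"))
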