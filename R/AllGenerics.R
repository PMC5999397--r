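#' Accessors for iceProfiler classes
#'
#' \code{densities} returns the raw density array of a
#' \linkS4class{TomoVolume}; \code{voxelSize} its voxel edge length in
#' ångström; \code{voxelSizeNm} the same in nm. \code{surfaceHeight}
#' evaluates an \linkS4class{InterfaceSurface} at (x, y) in nm.
#'
#' @param object,surface an iceProfiler object.
#' @param x,y coordinates in nm (vectors of equal length, or a grid when
#'   \code{grid = TRUE}).
#' @param grid if TRUE, evaluate on the outer grid of x and y and return a
#'   matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("densities", function(object) standardGeneric("densities"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("voxelSizeNm", function(object) standardGeneric("voxelSizeNm"))

#' @rdname accessors
#' @export
setGeneric("surfaceHeight",
           function(surface, x, y, grid = FALSE) standardGeneric("surfaceHeight"))

#' @rdname accessors
#' @export
setGeneric("surfaceTilt", function(surface) standardGeneric("surfaceTilt"))
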