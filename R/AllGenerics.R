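#' Accessors for wallthick objects
#'
#' Small accessor generics in the Bioconductor idiom; user code should use
#' these rather than reaching into slots.
#'
#' @param x a \code{LabelGrid}, \code{PotentialField},
#'   \code{UnitGradientField} or \code{ThicknessResult}.
#' @return \code{gridLabels}: the integer label array; \code{voxelSpacing}:
#'   mm per lattice step per axis; \code{gridOrigin}: physical position of the
#'   first voxel centre; \code{capFaces}: the Neumann cap face names;
#'   \code{labelGrid}: the underlying \code{LabelGrid}; \code{potential}: the
#'   potential array; \code{energyTrace}: recorded convergence energies;
#'   \code{converged}/\code{iterations}: solver status; \code{unitVectors}:
#'   list of unit-gradient component arrays; \code{validMask}: logical array
#'   of valid gradient voxels; \code{thicknessMap}, \code{distToOuterMap},
#'   \code{distToLumenMap}: the T, T+ and T- maps (mm, NA off the wall);
#'   \code{traceFlags}: integer per-voxel trace status.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridLabels", function(x) standardGeneric("gridLabels"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("capFaces", function(x) standardGeneric("capFaces"))
#' @rdname accessors
#' @export
setGeneric("labelGrid", function(x) standardGeneric("labelGrid"))
#' @rdname accessors
#' @export
setGeneric("potential", function(x) standardGeneric("potential"))
#' @rdname accessors
#' @export
setGeneric("energyTrace", function(x) standardGeneric("energyTrace"))
#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("iterations", function(x) standardGeneric("iterations"))
#' @rdname accessors
#' @export
setGeneric("unitVectors", function(x) standardGeneric("unitVectors"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("thicknessMap", function(x) standardGeneric("thicknessMap"))
#' @rdname accessors
#' @export
setGeneric("distToOuterMap", function(x) standardGeneric("distToOuterMap"))
#' @rdname accessors
#' @export
setGeneric("distToLumenMap", function(x) standardGeneric("distToLumenMap"))
#' @rdname accessors
#' @export
setGeneric("traceFlags", function(x) standardGeneric("traceFlags"))
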