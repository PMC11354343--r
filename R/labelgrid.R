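#' Construct a LabelGrid
#'
#' @param labels integer array of rank 2 or 3 with values \code{EXTERIOR} (0),
#'   \code{LUMEN} (1), \code{WALL} (2).
#' @param spacing numeric scalar or per-axis vector, mm per lattice step.
#' @param origin physical coordinate (mm) of the centre of voxel (0,...,0);
#'   defaults to the zero vector.
#' @param capFaces character vector of lattice faces treated as vessel end
#'   caps (Neumann condition), e.g. \code{c("z0")}; see
#'   \code{\linkS4class{LabelGrid}}.
#' @return a validated \code{LabelGrid}.
#' @examples
#' lab <- matrix(EXTERIOR, 9, 9)
#' lab[3:7, 3:7] <- WALL
#' lab[5, 5] <- LUMEN
#' g <- LabelGrid(lab, spacing = 0.5)
#' voxelSpacing(g)
#' @export
LabelGrid <- function(labels, spacing, origin = NULL, capFaces = character(0)) {
  if (is.null(dim(labels))) stop("labels must be a matrix or array")
  rank <- length(dim(labels))
  storage.mode(labels) <- "integer"
  if (length(spacing) == 1L) spacing <- rep(spacing, rank)
  if (is.null(origin)) origin <- rep(0, rank)
  methods::new("LabelGrid",
    labels = labels, spacing = as.numeric(spacing),
    origin = as.numeric(origin), capFaces = as.character(capFaces)
  )
}

#' @rdname accessors
#' @export
setMethod("gridLabels", "LabelGrid", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LabelGrid", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("gridOrigin", "LabelGrid", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("capFaces", "LabelGrid", function(x) x@capFaces)

#' @export
setMethod("dim", "LabelGrid", function(x) dim(x@labels))

setMethod("show", "LabelGrid", function(object) {
  d <- dim(object@labels)
  cnt <- labelCounts(object)
  cat(sprintf(
    "LabelGrid: %s lattice, spacing %s mm\n",
    paste(d, collapse = " x "),
    paste(signif(object@spacing, 4), collapse = " x ")
  ))
  cat(sprintf(
    "  exterior %d | lumen %d | wall %d voxels\n",
    cnt["exterior"], cnt["lumen"], cnt["wall"]
  ))
  if (length(object@capFaces)) {
    cat("  Neumann cap faces:", paste(object@capFaces, collapse = ", "), "\n")
  }
})

#' Count voxels per label
#'
#' @param grid a \code{LabelGrid}.
#' @return named integer vector with entries \code{exterior}, \code{lumen},
#'   \code{wall}.
#' @export
labelCounts <- function(grid) {
  lab <- grid@labels
  c(
    exterior = sum(lab == EXTERIOR),
    lumen = sum(lab == LUMEN),
    wall = sum(lab == WALL)
  )
}

#' Validate a segmentation lattice before measurement
#'
#' Checks that only the three defined label codes occur and that the wall (the
#' measurement domain) is non-empty, and reports per-label voxel counts.  A
#' lumen- or exterior-free grid is allowed through construction but rejected
#' here, because the Laplace problem then has only one Dirichlet boundary.
#'
#' @param grid a \code{LabelGrid}.
#' @param quiet suppress the count report message.
#' @return the grid, unchanged, invisibly carrying the counts as attribute
#'   \code{"labelCounts"}.
#' @examples
#' g <- generatePhantom(phantomSpec("circular_ring", resolution = 5))
#' g <- validateLabels(g, quiet = TRUE)
#' @export
validateLabels <- function(grid, quiet = FALSE) {
  methods::validObject(grid)  # unknown codes rejected here, naming them
  cnt <- labelCounts(grid)
  if (cnt["wall"] == 0L) stop("no wall to measure (zero WALL voxels)")
  if (cnt["lumen"] == 0L) {
    stop("no LUMEN voxels: the inner Dirichlet boundary is missing")
  }
  if (cnt["exterior"] == 0L) {
    stop("no EXTERIOR voxels: the outer Dirichlet boundary is missing")
  }
  if (!quiet) {
    message(sprintf(
      "labels ok: %d exterior, %d lumen, %d wall voxels",
      cnt["exterior"], cnt["lumen"], cnt["wall"]
    ))
  }
  attr(grid, "labelCounts") <- cnt
  grid
}

## Require an isotropic grid (single h); measurement stages call this.
.isotropicSpacing <- function(grid) {
  sp <- grid@spacing
  if (diff(range(sp)) > 1e-9 * mean(sp)) {
    stop(
      "grid spacing is anisotropic (", paste(signif(sp, 4), collapse = ", "),
      " mm); run resampleIsotropic() first"
    )
  }
  mean(sp)
}

## 0-based index -> physical coordinate helpers
.voxelCoords <- function(grid) {
  d <- dim(grid@labels)
  lapply(seq_along(d), function(k) {
    grid@origin[k] + (seq_len(d[k]) - 1) * grid@spacing[k]
  })
}
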