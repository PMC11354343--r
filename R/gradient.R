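#' Sobel-Feldman gradient of the potential field
#'
#' Computes the raw gradient per voxel by separable Sobel-Feldman filtering:
#' a [1,2,1]/4 smoothing kernel along every axis except the derivative axis,
#' and the spacing-2 central difference [-1,0,1]/2 along it (overall
#' normalization 1/8 in 2D and 1/32 in 3D, so a unit-slope ramp yields unit
#' gradient).  The sign convention is that a component is positive where phi
#' increases with the coordinate.  Replicate padding is used at lattice
#' borders; values outside the wall are computed (and are needed for
#' interpolation near the boundaries) but carry no measurement meaning deep
#' inside the clamped regions.  Components are in lattice units; physical
#' lengths are recovered downstream via the grid spacing.
#'
#' @param field a solved (or at least initialized) \code{PotentialField}.
#' @return a list of component arrays (one per axis) with the grid attached
#'   as attribute \code{"grid"}.
#' @seealso \code{\link{normalizeGradient}}
#' @export
sobelGradient <- function(field) {
  phi <- field@phi
  rank <- length(dim(phi))
  smooth <- c(1, 2, 1) / 4
  diffk <- c(-1, 0, 1) / 2   # correlation form: (phi[i+1] - phi[i-1]) / 2
  comps <- lapply(seq_len(rank), function(ax) {
    g <- .separableFilter(phi, smooth, setdiff(seq_len(rank), ax))
    .stencilApply(g, .axisKernel(diffk, ax, rank))
  })
  names(comps) <- .axisLetters[seq_len(rank)]
  attr(comps, "grid") <- field@grid
  comps
}

#' Normalize a raw gradient into a unit direction field
#'
#' Divides each voxel's gradient by its magnitude; voxels with magnitude
#' below \code{eps} are flagged invalid (their stored components are zeroed).
#' Invalidity is data, not an error: deep clamped regions are legitimately
#' flat.
#'
#' @param gradient component list from \code{\link{sobelGradient}}.
#' @param eps magnitude floor (default 1e-8).
#' @param grid the \code{LabelGrid}; defaults to the one attached to
#'   \code{gradient}.
#' @return a \code{UnitGradientField}.
#' @export
normalizeGradient <- function(gradient, eps = 1e-8, grid = NULL) {
  if (is.null(grid)) grid <- attr(gradient, "grid")
  if (is.null(grid)) stop("no grid attached to the gradient; pass `grid`")
  mag2 <- Reduce(`+`, lapply(gradient, function(a) a^2))
  mag <- sqrt(mag2)
  valid <- mag >= eps
  safe <- ifelse(valid, mag, 1)
  n <- lapply(gradient, function(a) ifelse(valid, a / safe, 0))
  methods::new("UnitGradientField",
    n = n, valid = valid, grid = grid, eps = eps
  )
}

#' @rdname accessors
#' @export
setMethod("unitVectors", "UnitGradientField", function(x) x@n)
#' @rdname accessors
#' @export
setMethod("validMask", "UnitGradientField", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("labelGrid", "UnitGradientField", function(x) x@grid)

setMethod("show", "UnitGradientField", function(object) {
  cat(sprintf(
    "UnitGradientField: %s, %.2f%% voxels valid (eps = %g)\n",
    paste(dim(object@valid), collapse = " x "),
    100 * mean(object@valid), object@eps
  ))
})

## Fast internal direction sampler: multilinear interpolation of the stored
## unit components followed by renormalization; no bounds checks (the tracer
## polices bounds).  Returns an m x rank matrix with NA rows where the
## interpolated magnitude falls below eps.
.sampleDirectionRaw <- function(fieldU, P) {
  v <- .interpLinear(fieldU@n, P)
  mag <- sqrt(rowSums(v^2))
  bad <- mag < fieldU@eps
  mag[bad] <- 1
  v <- v / mag
  v[bad, ] <- NA_real_
  v
}

#' Sample the streamline direction at continuous positions
#'
#' Multilinear interpolation of the unit-field components followed by
#' renormalization (interpolating the already-normalized field keeps the
#' direction near boundaries from being dominated by the large raw-gradient
#' magnitudes of the clamped regions).  Positions are 0-based voxel
#' coordinates with voxel centres at integers.
#'
#' @param fieldU a \code{UnitGradientField}.
#' @param p numeric vector (one position) or m x rank matrix.
#' @return an m x rank matrix of unit vectors; rows are NA where the
#'   interpolated magnitude is below \code{eps} (e.g. all surrounding voxels
#'   invalid).  Positions outside the lattice are an error: callers tracing
#'   paths must detect out-of-bounds themselves.
#' @export
sampleDirection <- function(fieldU, p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  d <- dim(fieldU@valid)
  if (ncol(p) != length(d)) stop("position rank does not match the field")
  if (any(p < 0) || any(sweep(p, 2L, d - 1L, `>`))) {
    stop("position outside the lattice")
  }
  .sampleDirectionRaw(fieldU, p)
}
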