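#' Label codes for segmentation lattices
#'
#' Fixed integer codes used throughout the package: \code{EXTERIOR = 0}
#' (tissue outside the outer wall, Dirichlet potential 1), \code{LUMEN = 1}
#' (blood-carrying interior, Dirichlet potential 0) and \code{WALL = 2}
#' (the vessel wall, the measurement domain).  Input images using other
#' conventions are remapped at read time (see \code{\link{readLabelImage}}).
#'
#' @name labelCodes
#' @aliases EXTERIOR LUMEN WALL
NULL

#' @rdname labelCodes
#' @export
EXTERIOR <- 0L
#' @rdname labelCodes
#' @export
LUMEN <- 1L
#' @rdname labelCodes
#' @export
WALL <- 2L

.KNOWN_LABELS <- c(EXTERIOR, LUMEN, WALL)

#' LabelGrid: a segmentation lattice with physical metadata
#'
#' The central data container: an integer lattice of rank 2 or 3 holding the
#' labels \code{EXTERIOR}/\code{LUMEN}/\code{WALL}, together with the physical
#' voxel spacing (mm per lattice step, one value per axis), the physical
#' coordinate of the centre of voxel (0,...,0), and the set of lattice boundary
#' faces flagged as vessel end caps.  Cap faces receive a zero-normal-gradient
#' (Neumann) condition in the Laplace solve so that streamlines stay parallel
#' to artificial cut planes.  Face names are \code{"x0"}, \code{"x1"},
#' \code{"y0"}, ... where \code{0}/\code{1} denote the low/high face of each
#' axis.
#'
#' @slot labels integer array of rank 2 or 3 with values 0/1/2.
#' @slot spacing numeric, mm per lattice step along each axis.
#' @slot origin numeric, physical position (mm) of the first voxel centre.
#' @slot capFaces character, subset of the face names above.
#'
#' @seealso \code{\link{LabelGrid}}, \code{\link{validateLabels}}
#' @export
setClass("LabelGrid",
  representation(
    labels = "array",
    spacing = "numeric",
    origin = "numeric",
    capFaces = "character"
  )
)

setValidity("LabelGrid", function(object) {
  d <- dim(object@labels)
  rank <- length(d)
  msgs <- character(0)
  if (!rank %in% c(2L, 3L)) {
    msgs <- c(msgs, "labels must be a rank-2 or rank-3 array")
  }
  bad <- setdiff(unique(as.vector(object@labels)), .KNOWN_LABELS)
  if (length(bad)) {
    msgs <- c(msgs, paste0(
      "unknown label code(s): ", paste(sort(bad), collapse = ", "),
      " (expected EXTERIOR=0, LUMEN=1, WALL=2)"
    ))
  }
  if (length(object@spacing) != rank) {
    msgs <- c(msgs, "spacing must have one entry per lattice axis")
  }
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0)) {
    msgs <- c(msgs, "spacing entries must be strictly positive")
  }
  if (length(object@origin) != rank) {
    msgs <- c(msgs, "origin must have one entry per lattice axis")
  }
  if (length(object@capFaces) &&
      !all(object@capFaces %in% .faceNames(rank))) {
    msgs <- c(msgs, paste0(
      "capFaces must be a subset of {",
      paste(.faceNames(rank), collapse = ", "), "}"
    ))
  }
  if (length(msgs)) msgs else TRUE
})

#' PotentialField: solution state of the Laplace boundary-value problem
#'
#' Scalar potential per voxel on a \code{LabelGrid}, clamped to 0 on the lumen
#' and 1 on the exterior, harmonic (to solver tolerance) on the wall.  Carries
#' the convergence flag, iteration count and the recorded energy trace (RMS
#' per-wall-voxel change between consecutive Jacobi iterates).
#'
#' @slot phi numeric array, same dimensions as the grid labels.
#' @slot grid the \code{LabelGrid} solved on.
#' @slot converged logical.
#' @slot iterations integer, Jacobi iterations performed.
#' @slot energyTrace numeric, energy values at the recorded checkpoints.
#'
#' @seealso \code{\link{solveLaplace}}, \code{\link{initPotential}}
#' @export
setClass("PotentialField",
  representation(
    phi = "array",
    grid = "LabelGrid",
    converged = "logical",
    iterations = "integer",
    energyTrace = "numeric"
  )
)

setValidity("PotentialField", function(object) {
  if (!identical(dim(object@phi), dim(object@grid@labels))) {
    return("phi dimensions must match the grid labels")
  }
  lab <- object@grid@labels
  if (any(object@phi[lab == LUMEN] != 0)) {
    return("phi must equal 0 on all LUMEN voxels")
  }
  if (any(object@phi[lab == EXTERIOR] != 1)) {
    return("phi must equal 1 on all EXTERIOR voxels")
  }
  rng <- range(object@phi)
  if (rng[1] < 0 || rng[2] > 1) {
    return("phi must satisfy 0 <= phi <= 1 (discrete maximum principle)")
  }
  TRUE
})

#' UnitGradientField: normalized potential gradient (streamline directions)
#'
#' Per-voxel unit vectors n = grad(phi) / ||grad(phi)|| stored as one component
#' array per lattice axis (lattice units; the upstream pipeline guarantees
#' isotropic spacing).  Voxels whose raw gradient magnitude falls below
#' \code{eps} are flagged invalid and their stored components are zero so that
#' interpolation never manufactures a direction from them.
#'
#' @slot n list of numeric arrays, one per axis.
#' @slot valid logical array, FALSE where the gradient magnitude < eps.
#' @slot grid the underlying \code{LabelGrid}.
#' @slot eps numeric magnitude floor.
#'
#' @seealso \code{\link{sobelGradient}}, \code{\link{normalizeGradient}},
#'   \code{\link{sampleDirection}}
#' @export
setClass("UnitGradientField",
  representation(
    n = "list",
    valid = "array",
    grid = "LabelGrid",
    eps = "numeric"
  )
)

setValidity("UnitGradientField", function(object) {
  rank <- length(dim(object@grid@labels))
  if (length(object@n) != rank) {
    return("one component array per lattice axis is required")
  }
  ok <- vapply(object@n, function(a) {
    identical(dim(a), dim(object@grid@labels))
  }, logical(1))
  if (!all(ok)) return("component dimensions must match the grid")
  if (!identical(dim(object@valid), dim(object@grid@labels))) {
    return("valid mask dimensions must match the grid")
  }
  TRUE
})

#' ThicknessResult: per-voxel thickness and path-length maps
#'
#' For every wall voxel: \code{thickness} T (mm), \code{distOuter} T+ (length
#' of the positive path, the distance to the outer wall) and \code{distLumen}
#' T- (length of the negative path, the distance to the lumen), with
#' T = T+ + T- wherever the trace status is ok.  Voxels outside the wall hold
#' NA.  \code{flags} records the per-voxel trace status (0 = ok,
#' 1 = invalid_gradient, 2 = max_steps, 3 = out_of_bounds).
#'
#' @slot thickness numeric array (mm).
#' @slot distOuter numeric array (mm).
#' @slot distLumen numeric array (mm).
#' @slot flags integer array (NA outside the wall).
#' @slot grid the \code{LabelGrid} measured on.
#' @slot diagnostics list: fraction of ok traces, mean/sd thickness, gamma.
#'
#' @seealso \code{\link{computeThickness}}, \code{\link{errorMetrics}}
#' @export
setClass("ThicknessResult",
  representation(
    thickness = "array",
    distOuter = "array",
    distLumen = "array",
    flags = "array",
    grid = "LabelGrid",
    diagnostics = "list"
  )
)

.FLAG_OK <- 0L
.FLAG_INVALID_GRADIENT <- 1L
.FLAG_MAX_STEPS <- 2L
.FLAG_OUT_OF_BOUNDS <- 3L
.FLAG_NAMES <- c(
  ok = 0L, invalid_gradient = 1L, max_steps = 2L, out_of_bounds = 3L
)

setValidity("ThicknessResult", function(object) {
  d <- dim(object@grid@labels)
  for (s in c("thickness", "distOuter", "distLumen", "flags")) {
    if (!identical(dim(slot(object, s)), d)) {
      return(paste(s, "dimensions must match the grid"))
    }
  }
  ok <- !is.na(object@flags) & object@flags == .FLAG_OK
  tp <- object@distOuter[ok]
  tm <- object@distLumen[ok]
  if (length(tp) && (any(tp < 0) || any(tm < 0))) {
    return("path lengths must be non-negative")
  }
  TRUE
})

#' PhantomSpec: parametric description of a validation phantom
#'
#' Describes one of the digital phantoms with analytically known uniform wall
#' thickness: a circular or elliptical ring (2D), a half-spherical or
#' half-ellipsoid shell, or a bent pipe whose axis is a quarter circle (3D).
#' In every case the lumen is the interior of the inner surface and the wall
#' is the set of points within Euclidean distance \code{d} of that surface on
#' the outside, so the ground-truth thickness is exactly \code{d} everywhere
#' (for ellipses/ellipsoids the outer boundary is the true offset surface, not
#' a scaled copy).
#'
#' @slot shape one of \code{"circular_ring"}, \code{"elliptical_ring"},
#'   \code{"half_spherical_shell"}, \code{"half_ellipsoid_shell"},
#'   \code{"bent_pipe"}.
#' @slot r numeric, inner radius (mm) for circle/sphere/pipe shapes.
#' @slot r1,r2,r3 numeric, inner semi-axes (mm) for ellipse/ellipsoid shapes.
#' @slot axisRadius numeric, radius (mm) of the quarter-circle pipe axis.
#' @slot d numeric, wall thickness (mm).
#' @slot resolution numeric, lattice steps per mm (h = 1/resolution).
#' @slot margin integer, exterior padding (voxels) on non-cap faces.
#'
#' @seealso \code{\link{phantomSpec}}, \code{\link{generatePhantom}}
#' @export
setClass("PhantomSpec",
  representation(
    shape = "character",
    r = "numeric",
    r1 = "numeric",
    r2 = "numeric",
    r3 = "numeric",
    axisRadius = "numeric",
    d = "numeric",
    resolution = "numeric",
    margin = "integer"
  )
)

.PHANTOM_SHAPES <- c(
  "circular_ring", "elliptical_ring",
  "half_spherical_shell", "half_ellipsoid_shell", "bent_pipe"
)

setValidity("PhantomSpec", function(object) {
  msgs <- character(0)
  if (!object@shape %in% .PHANTOM_SHAPES) {
    msgs <- c(msgs, paste0(
      "shape must be one of: ", paste(.PHANTOM_SHAPES, collapse = ", ")
    ))
  }
  if (!is.finite(object@d) || object@d <= 0) {
    msgs <- c(msgs, "wall thickness d must be > 0")
  }
  if (!is.finite(object@resolution) || object@resolution <= 0) {
    msgs <- c(msgs, "resolution must be > 0")
  }
  if (object@margin < 0L) msgs <- c(msgs, "margin must be >= 0")
  need <- switch(object@shape,
    circular_ring = ,
    half_spherical_shell = "r",
    bent_pipe = c("r", "axisRadius"),
    elliptical_ring = c("r1", "r2"),
    half_ellipsoid_shell = c("r1", "r2", "r3"),
    character(0)
  )
  for (s in need) {
    v <- slot(object, s)
    if (!is.finite(v) || v <= 0) {
      msgs <- c(msgs, paste0("slot '", s, "' must be > 0 for shape ",
                             object@shape))
    }
  }
  if (length(msgs)) msgs else TRUE
})
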