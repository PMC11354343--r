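#' Preprocessing control parameters
#'
#' Settings for the mask preprocessing applied before measurement: upsampling
#' with Gaussian smoothing (for coarse masks) and the interpolation order used
#' when resampling anisotropic grids.
#'
#' @param upsampleFactor positive integer; each voxel is split into
#'   \code{factor^rank} subvoxels (default 3, the factor used for in vivo
#'   masks before measurement).
#' @param gaussianSigma smoothing width in upsampled voxels (default 0.5);
#'   0 disables smoothing.
#' @param resampleOrder 0 (nearest) or 1 (linear) indicator interpolation for
#'   \code{\link{resampleIsotropic}}.
#' @return a list of class \code{"preprocessControl"}.
#' @export
preprocessControl <- function(upsampleFactor = 3L, gaussianSigma = 0.5,
                              resampleOrder = 1L) {
  upsampleFactor <- as.integer(upsampleFactor)
  stopifnot(
    upsampleFactor >= 1L, gaussianSigma >= 0,
    resampleOrder %in% c(0L, 1L)
  )
  structure(
    list(
      upsampleFactor = upsampleFactor,
      gaussianSigma = gaussianSigma,
      resampleOrder = as.integer(resampleOrder)
    ),
    class = "preprocessControl"
  )
}

## Argmax relabelling of per-label indicator scores with tie precedence
## WALL > LUMEN > EXTERIOR, so ties never erode the measurement domain.
## `scores` is an n x 3 matrix with columns in code order 0,1,2.
.argmaxLabel <- function(scores) {
  as.integer(max.col(scores, ties.method = "last") - 1L)
}

## Breach check: after smoothing, the wall must still separate lumen from
## exterior; a LUMEN voxel with an EXTERIOR voxel in its full (8/26-connected)
## neighbourhood is a breach.
.checkWallSeparates <- function(labels) {
  rank <- length(dim(labels))
  ext <- labels == EXTERIOR
  lum <- labels == LUMEN
  offsets <- as.matrix(expand.grid(rep(list(-1:1), rank)))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  for (m in seq_len(nrow(offsets))) {
    hit <- lum & .shiftReplicate(ext, offsets[m, ])
    if (any(hit)) {
      at <- arrayInd(which(hit)[1], dim(labels))
      stop(
        "wall breached: lumen touches exterior near voxel (",
        paste(at, collapse = ", "), ")"
      )
    }
  }
  invisible(TRUE)
}

#' Resample an anisotropic label grid to isotropic spacing
#'
#' Anisotropic voxels bias both the finite-difference Laplacian and the traced
#' path lengths, so measurement requires a single spacing h.  The target
#' spacing is the minimum input spacing (upsampling, never downsampling, so
#' thin walls are not destroyed).  Each label's indicator is resampled
#' independently and the output label is the indicator argmax, ties broken by
#' the precedence WALL > LUMEN > EXTERIOR.
#'
#' @param grid a \code{LabelGrid}.
#' @param order interpolation order for the indicators: 0 nearest, 1 linear.
#' @return an isotropic \code{LabelGrid}; the input itself when it is already
#'   isotropic.
#' @export
resampleIsotropic <- function(grid, order = 1L) {
  sp <- grid@spacing
  if (diff(range(sp)) <= 1e-9 * mean(sp)) return(grid)
  h <- min(sp)
  d <- dim(grid@labels)
  rank <- length(d)
  newDim <- floor((d - 1L) * sp / h) + 1L
  ## sample positions in old 0-based voxel coordinates
  ax <- lapply(seq_len(rank), function(k) (seq_len(newDim[k]) - 1) * h / sp[k])
  P <- as.matrix(expand.grid(ax))
  if (order == 0L) {
    near <- .nearestVoxel(P)
    strides <- cumprod(c(1L, d[-rank]))
    idx <- 1 + as.vector(near %*% strides)
    newLab <- grid@labels[idx]
  } else {
    scores <- sapply(.KNOWN_LABELS, function(code) {
      ind <- array(as.numeric(grid@labels == code), d)
      .interpLinear(list(ind), P)[, 1]
    })
    newLab <- .argmaxLabel(scores)
  }
  LabelGrid(array(newLab, newDim),
    spacing = rep(h, rank),
    origin = grid@origin, capFaces = grid@capFaces
  )
}

#' Upsample a label grid and smooth the label indicators
#'
#' Splits every voxel into \code{factor^rank} subvoxels (spacing divided by
#' the factor), Gaussian-smooths each label's indicator, and relabels by
#' indicator argmax (ties: WALL > LUMEN > EXTERIOR).  Smoothing rounds off
#' staircase artefacts of coarse masks while keeping a crisp label boundary
#' for the solver's Dirichlet clamps.  After smoothing, the wall must still
#' separate lumen from exterior; a breach is an error naming the location.
#'
#' @param grid an isotropic \code{LabelGrid}.
#' @param control a \code{\link{preprocessControl}}.
#' @return the upsampled \code{LabelGrid}.
#' @examples
#' g <- generatePhantom(phantomSpec("circular_ring", resolution = 5))
#' g3 <- upsampleAndSmooth(g, preprocessControl(upsampleFactor = 3))
#' voxelSpacing(g3) / voxelSpacing(g)
#' @export
upsampleAndSmooth <- function(grid, control = preprocessControl()) {
  h <- .isotropicSpacing(grid)
  f <- control$upsampleFactor
  sigma <- control$gaussianSigma
  if (f == 1L && sigma == 0) return(grid)
  d <- dim(grid@labels)
  rank <- length(d)
  ## nearest replication: exact factor^rank scaling of label counts
  idx <- lapply(d, function(n) rep(seq_len(n), each = f))
  lab <- do.call(`[`, c(list(grid@labels), idx, list(drop = FALSE)))
  newSpacing <- rep(h / f, rank)
  newOrigin <- grid@origin - h / 2 + h / (2 * f)
  if (sigma > 0) {
    w <- .gaussianWeights(sigma)
    scores <- sapply(.KNOWN_LABELS, function(code) {
      ind <- array(as.numeric(lab == code), dim(lab))
      as.vector(.separableFilter(ind, w, seq_len(rank)))
    })
    lab <- array(.argmaxLabel(scores), dim(lab))
    .checkWallSeparates(lab)
  }
  LabelGrid(lab,
    spacing = newSpacing, origin = newOrigin,
    capFaces = grid@capFaces
  )
}
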