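#' ROI morphometrics
#'
#' Region-of-interest summaries of a thickness measurement: area (2D) or
#' volume (3D), the normalized index (ROI area divided by total vessel area,
#' where total vessel area = lumen area + wall area), and mean/standard
#' deviation of the wall thickness and of the distance to the lumen within
#' the ROI.  Standard deviations are population (divide-by-N) values.
#'
#' @name roiStatistics
NULL

.ROI_TYPES <- c(
  "lumen", "outer_wall", "calcification", "hemorrhage",
  "lipid_pool", "loose_matrix", "other"
)

#' Assemble a set of ROIs on a grid
#'
#' @param masks named list of logical arrays on the grid lattice (ROIs may
#'   overlap; plaque-component ROIs typically lie inside the outer-wall ROI).
#' @param types character vector, one type per mask, from \code{lumen},
#'   \code{outer_wall}, \code{calcification}, \code{hemorrhage},
#'   \code{lipid_pool}, \code{loose_matrix}, \code{other}.
#' @param grid the \code{LabelGrid} the masks live on.
#' @return a list of class \code{"ROISet"}.
#' @export
roiSet <- function(masks, types, grid) {
  stopifnot(is.list(masks), length(masks) == length(types))
  types <- vapply(types, function(t) match.arg(t, .ROI_TYPES), character(1))
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), dim(grid@labels))) {
      stop("ROI mask '", nm, "' does not match the grid dimensions")
    }
  }
  structure(list(masks = masks, types = unname(types), grid = grid),
            class = "ROISet")
}

#' Physical area or volume of an ROI mask
#'
#' Voxel count times h^rank: mm^2 on 2D grids, mm^3 on 3D grids.  An empty
#' mask has area 0.
#'
#' @param mask logical array on the grid lattice.
#' @param grid the \code{LabelGrid}.
#' @return scalar area/volume.
#' @export
roiArea <- function(mask, grid) {
  if (!identical(dim(mask), dim(grid@labels))) {
    stop("mask does not match the grid dimensions")
  }
  sum(mask) * prod(grid@spacing)
}

#' Normalized index of an ROI
#'
#' ROI area divided by the total vessel area, where the total is the lumen
#' area plus the wall area.  The lumen and outer-wall indices of one sample
#' therefore sum to 1.
#'
#' @param roiArea,lumenArea,wallArea areas in consistent units.
#' @return dimensionless index.
#' @export
normalizedIndex <- function(roiArea, lumenArea, wallArea) {
  total <- lumenArea + wallArea
  if (!is.finite(total) || total <= 0) {
    stop("total vessel area (lumen + wall) must be positive")
  }
  roiArea / total
}

#' Thickness and distance-to-lumen statistics within an ROI
#'
#' Statistics are voxel-weighted over the intersection of the ROI with the
#' wall, restricted to ok-flagged traces.
#'
#' @param mask logical array on the grid lattice.
#' @param result a \code{ThicknessResult}.
#' @return list with \code{thicknessMean}, \code{thicknessSd},
#'   \code{distLumenMean}, \code{distLumenSd} (mm) and the voxel count
#'   \code{n}.
#' @export
roiThicknessStats <- function(mask, result) {
  if (!identical(dim(mask), dim(result@grid@labels))) {
    stop("mask does not match the grid dimensions")
  }
  sel <- mask & result@grid@labels == WALL &
    !is.na(result@flags) & result@flags == .FLAG_OK
  n <- sum(sel)
  if (n == 0L) {
    stop("ROI does not intersect ok-flagged wall voxels (count 0)")
  }
  tt <- result@thickness[sel]
  dl <- result@distLumen[sel]
  list(
    thicknessMean = mean(tt), thicknessSd = .popSd(tt),
    distLumenMean = mean(dl), distLumenSd = .popSd(dl),
    n = n
  )
}

#' Tabulate ROI morphometrics
#'
#' Builds the per-ROI report: area, normalized index, thickness mean/sd and
#' distance-to-lumen mean/sd.  The lumen and wall areas entering the
#' normalized index are taken from the ROIs typed \code{lumen} and
#' \code{outer_wall} (falling back to the grid's own LUMEN/WALL labels if
#' either is absent).  Lumen-type ROIs get no thickness statistics: they do
#' not intersect the wall.
#'
#' @param rois an \code{\link{roiSet}}.
#' @param result a \code{ThicknessResult} on the same grid.
#' @return a data.frame with one row per ROI.
#' @export
roiReport <- function(rois, result) {
  grid <- rois$grid
  areas <- vapply(rois$masks, roiArea, numeric(1), grid = grid)
  lum <- which(rois$types == "lumen")[1]
  wal <- which(rois$types == "outer_wall")[1]
  lumenArea <- if (!is.na(lum)) areas[lum] else {
    sum(grid@labels == LUMEN) * prod(grid@spacing)
  }
  wallArea <- if (!is.na(wal)) areas[wal] else {
    sum(grid@labels == WALL) * prod(grid@spacing)
  }
  rows <- lapply(seq_along(rois$masks), function(i) {
    base <- data.frame(
      roi = names(rois$masks)[i],
      type = rois$types[i],
      area = areas[i],
      normalizedIndex = normalizedIndex(areas[i], lumenArea, wallArea),
      thicknessMean = NA_real_, thicknessSd = NA_real_,
      distLumenMean = NA_real_, distLumenSd = NA_real_,
      n = NA_integer_,
      stringsAsFactors = FALSE
    )
    if (rois$types[i] != "lumen") {
      st <- roiThicknessStats(rois$masks[[i]], result)
      base$thicknessMean <- st$thicknessMean
      base$thicknessSd <- st$thicknessSd
      base$distLumenMean <- st$distLumenMean
      base$distLumenSd <- st$distLumenSd
      base$n <- st$n
    }
    base
  })
  do.call(rbind, rows)
}
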