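#' Read a label image into a LabelGrid
#'
#' 3D grids are read from NIfTI (\code{.nii}/\code{.nii.gz}), taking the
#' voxel spacing from the pixdim header and the origin from the translation
#' of the stored xform; 2D grids from PNG or TIFF, which carry no physical
#' metadata, so \code{spacing} must be supplied.  Input values are remapped
#' through \code{mapping}, whose names give the package codes and whose
#' values give the codes used in the file.  Values not covered by the mapping
#' are rejected by validation, naming the offending codes.
#'
#' @param path image file path.
#' @param mapping named numeric vector with entries \code{exterior},
#'   \code{lumen}, \code{wall} giving the label values used in the file.
#' @param spacing mm per lattice step (scalar or per-axis); required for
#'   PNG/TIFF, overrides the header when given for NIfTI.
#' @param origin physical coordinate of the first voxel centre; defaults to
#'   the NIfTI header translation, or zero for 2D formats.
#' @param capFaces Neumann cap faces, see \code{\linkS4class{LabelGrid}}.
#' @return a \code{LabelGrid}.
#' @export
readLabelImage <- function(path,
                           mapping = c(exterior = 0, lumen = 1, wall = 2),
                           spacing = NULL, origin = NULL,
                           capFaces = character(0)) {
  stopifnot(all(c("exterior", "lumen", "wall") %in% names(mapping)))
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    im <- RNifti::readNifti(path)
    vals <- as.array(im)
    if (length(dim(vals)) > 3L) vals <- drop(vals)
    if (is.null(spacing)) spacing <- RNifti::pixdim(im)[seq_along(dim(vals))]
    if (is.null(origin)) {
      xf <- RNifti::xform(im)
      origin <- xf[seq_along(dim(vals)), ncol(xf)]
    }
  } else if (ext %in% c(".png", ".tif", ".tiff")) {
    vals <- if (ext == ".png") png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(vals)) == 3L) vals <- vals[, , 1]   # first channel
    vals <- round(vals * 255)
    if (is.null(spacing)) {
      stop("2D images carry no physical metadata: supply `spacing` (mm/pixel)")
    }
    if (is.null(origin)) origin <- rep(0, 2L)
  } else {
    stop("unsupported image format: ", path)
  }
  if (max(abs(vals - round(vals))) > 1e-6) {
    stop("image does not hold integer labels")
  }
  vals <- round(vals)
  lab <- array(NA_integer_, dim(vals))
  lab[vals == mapping[["exterior"]]] <- EXTERIOR
  lab[vals == mapping[["lumen"]]] <- LUMEN
  lab[vals == mapping[["wall"]]] <- WALL
  if (anyNA(lab)) {
    bad <- sort(unique(vals[is.na(lab)]))
    stop(
      "label value(s) not covered by the mapping: ",
      paste(bad, collapse = ", ")
    )
  }
  LabelGrid(lab, spacing = spacing, origin = origin, capFaces = capFaces)
}

#' Write a LabelGrid to an image file
#'
#' The inverse of \code{\link{readLabelImage}}: 3D grids go to NIfTI with
#' spacing and origin recorded in the header; 2D grids to PNG/TIFF with the
#' label codes stored as 8-bit grey values (a write-then-read round trip
#' reproduces labels and, for NIfTI, spacing and origin exactly).
#'
#' @param grid a \code{LabelGrid}.
#' @param path output path; format chosen by extension.
#' @param mapping file values to use for the three codes (default identity).
#' @return the path, invisibly.
#' @export
writeLabelImage <- function(grid, path,
                            mapping = c(exterior = 0, lumen = 1, wall = 2)) {
  lab <- grid@labels
  vals <- array(0, dim(lab))
  vals[lab == EXTERIOR] <- mapping[["exterior"]]
  vals[lab == LUMEN] <- mapping[["lumen"]]
  vals[lab == WALL] <- mapping[["wall"]]
  .writeVolume(vals, grid, path, integerData = TRUE)
}

## Shared volume writer for label and float maps.
.writeVolume <- function(vals, grid, path, integerData = FALSE) {
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  rank <- length(dim(vals))
  if (ext %in% c(".nii", ".nii.gz")) {
    im <- RNifti::asNifti(vals, internal = FALSE)
    sp <- grid@spacing
    RNifti::pixdim(im) <- sp
    m <- diag(4)
    m[seq_len(rank), seq_len(rank)] <- diag(sp, rank)
    m[seq_len(rank), 4] <- grid@origin
    xf <- structure(m, code = 2L)
    RNifti::sform(im) <- xf
    RNifti::qform(im) <- xf
    RNifti::writeNifti(im, path)
  } else if (ext == ".png") {
    if (rank != 2L) stop("PNG output is 2D only")
    if (!integerData) stop("PNG holds labels, not float maps; use TIFF")
    png::writePNG(vals / 255, path)
  } else if (ext %in% c(".tif", ".tiff")) {
    if (rank != 2L) stop("TIFF output is 2D only; use NIfTI for volumes")
    if (!integerData) {
      stop("float maps are written as NIfTI (TIFF/PNG hold 8-bit labels)")
    }
    tiff::writeTIFF(vals / 255, path)
  } else {
    stop("unsupported image format: ", path)
  }
  invisible(path)
}

#' Write measurement maps and summaries to a directory
#'
#' Persists the thickness, distance-to-outer-wall and distance-to-lumen maps
#' as float NIfTI aligned to the input grid (NA encoded as -1), the
#' trace-status flags as a label volume, and a one-row summary CSV.
#'
#' @param result a \code{ThicknessResult}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix (default \code{"wallthick"}).
#' @return named character vector of the files written, invisibly.
#' @export
writeMaps <- function(result, dir, prefix = "wallthick") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- result@grid
  mapExt <- ".nii.gz"
  noNA <- function(a) {
    a[is.na(a)] <- -1
    a
  }
  files <- c(
    thickness = file.path(dir, paste0(prefix, "_thickness", mapExt)),
    distOuter = file.path(dir, paste0(prefix, "_dist_outer", mapExt)),
    distLumen = file.path(dir, paste0(prefix, "_dist_lumen", mapExt)),
    flags = file.path(dir, paste0(prefix, "_flags", mapExt)),
    summary = file.path(dir, paste0(prefix, "_summary.csv"))
  )
  .writeVolume(noNA(result@thickness), grid, files[["thickness"]])
  .writeVolume(noNA(result@distOuter), grid, files[["distOuter"]])
  .writeVolume(noNA(result@distLumen), grid, files[["distLumen"]])
  fl <- result@flags
  fl[is.na(fl)] <- 255L
  .writeVolume(fl, grid, files[["flags"]], integerData = TRUE)
  dg <- result@diagnostics
  utils::write.csv(
    data.frame(
      fractionOk = dg$fractionOk,
      meanThickness = dg$meanThickness,
      sdThickness = dg$sdThickness,
      gamma = dg$gamma
    ),
    files[["summary"]],
    row.names = FALSE
  )
  invisible(files)
}
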