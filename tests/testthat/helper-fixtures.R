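# Shared fixtures, all built in code.  Pipeline runs on the validation
# phantoms are cached for the session: several test files interrogate the
# same solve/trace results.

.runCache <- new.env(parent = emptyenv())

cachedRun <- function(shape, res, d = 1.5) {
  key <- paste(shape, res, d, sep = "|")
  if (!exists(key, envir = .runCache)) {
    run <- suppressWarnings(runPipeline(
      phantomSpec(shape, resolution = res, d = d),
      quiet = TRUE
    ))
    assign(key, run, envir = .runCache)
  }
  get(key, envir = .runCache)
}

cachedSweep <- function(shape, resolutions, d = 1.5) {
  rows <- lapply(resolutions, function(res) {
    run <- cachedRun(shape, res, d)
    em <- errorMetrics(run$thickness, d)
    data.frame(
      resolution = res, meanThickness = run$stats$meanThickness,
      bias = em$bias, rmse = em$rmse, mad = em$mad
    )
  })
  do.call(rbind, rows)
}

# Flat 2D slab: lumen | wall | exterior bands along x, Neumann caps on the
# y faces.  Wall occupies `wallCols` columns of width h each.
slabGrid <- function(wallCols = 15L, h = 0.1, ny = 8L, pad = 3L) {
  nx <- 2L * pad + wallCols
  lab <- matrix(WALL, nx, ny)
  lab[seq_len(pad), ] <- LUMEN
  lab[(pad + wallCols + 1L):nx, ] <- EXTERIOR
  LabelGrid(lab, spacing = h, capFaces = c("y0", "y1"))
}

# Full concentric spherical shell (no caps): closed-form potential oracle.
fullShellGrid <- function(res, rIn = 1.5, rOut = 3.0, margin = 4L) {
  h <- 1 / res
  n <- 2L * (as.integer(ceiling(rOut / h)) + margin)
  x <- (seq_len(n) - 1 - (n - 1) / 2) * h
  R <- sqrt(outer(outer(x^2, x^2, `+`), x^2, `+`))
  lab <- array(EXTERIOR, c(n, n, n))
  lab[R <= rOut] <- WALL
  lab[R <= rIn] <- LUMEN
  LabelGrid(lab, spacing = h, origin = rep(x[1], 3))
}

cachedShellSolve <- function(res) {
  key <- paste("fullshell", res, sep = "|")
  if (!exists(key, envir = .runCache)) {
    assign(key, solveLaplace(fullShellGrid(res)), envir = .runCache)
  }
  get(key, envir = .runCache)
}

# Physical radius of every voxel centre of a centred grid.
radiusArray <- function(grid) {
  co <- lapply(seq_along(dim(grid)), function(k) {
    gridOrigin(grid)[k] + (seq_len(dim(grid)[k]) - 1) * voxelSpacing(grid)[k]
  })
  r2 <- outer(co[[1]]^2, co[[2]]^2, `+`)
  if (length(co) == 3L) r2 <- outer(r2, co[[3]]^2, `+`)
  sqrt(r2)
}
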