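test_that("paths through a linear slab field measure the band width", {
  g <- slabGrid(wallCols = 15L, h = 0.1, ny = 8L, pad = 3L)
  f <- solveLaplace(g)
  u <- normalizeGradient(sobelGradient(f))
  h <- voxelSpacing(g)[1]
  cfg <- tracerControl()
  # positive path from the lumen-adjacent wall voxel to the far face
  tr <- tracePath(u, c(4L, 4L), +1, cfg)
  expect_identical(tr$status, "ok")
  # 0-based start row 3; exit once past 17.5, midway to the first exterior row
  distToFace <- (17.5 - 3) * h
  expect_lt(abs(tr$length - distToFace), cfg$gamma * h + 1e-9)
  # negative path exits immediately into the lumen
  trn <- tracePath(u, c(4L, 4L), -1, cfg)
  expect_identical(trn$status, "ok")
  expect_lte(trn$length, 2 * cfg$gamma * h)

  expect_error(tracePath(u, c(1L, 1L), +1, cfg), "not a WALL")

  res <- computeThickness(u)
  tt <- thicknessMap(res)
  wall <- gridLabels(g) == WALL
  expect_true(all(abs(tt[wall] - 1.5) <= 2 * cfg$gamma * h + 1e-9))
})

test_that("an invalid starting gradient is flagged with zero length", {
  lab <- matrix(WALL, 4, 4)
  phi <- array(0.5, c(4, 4))
  f <- methods::new("PotentialField",
    phi = phi, grid = LabelGrid(lab, spacing = 1),
    converged = TRUE, iterations = 0L, energyTrace = numeric(0)
  )
  u <- normalizeGradient(sobelGradient(f))
  tr <- tracePath(u, c(2L, 2L), +1)
  expect_identical(tr$status, "invalid_gradient")
  expect_equal(tr$length, 0)
})

test_that("annulus path lengths match the radial closed form", {
  run <- cachedRun("circular_ring", 20)
  u <- run$gradient
  grid <- run$grid
  lab <- gridLabels(grid)
  R <- radiusArray(grid)
  wallPos <- which(lab == WALL, arr.ind = TRUE)
  set.seed(11)
  for (i in sample(nrow(wallPos), 20)) {
    v <- wallPos[i, ]
    rho <- R[v[1], v[2]]
    tr <- tracePath(u, v, +1)
    expect_identical(tr$status, "ok")
    expect_lt(abs(tr$length - (3.0 - rho)), 0.1)
  }
})

test_that("thickness decomposes exactly into the two path lengths", {
  run <- cachedRun("circular_ring", 10)
  res <- run$thickness
  ok <- !is.na(traceFlags(res)) & traceFlags(res) == 0L
  expect_true(any(ok))
  expect_identical(
    thicknessMap(res)[ok],
    distToOuterMap(res)[ok] + distToLumenMap(res)[ok]
  )
  expect_true(all(distToOuterMap(res)[ok] >= 0))
  expect_true(all(distToLumenMap(res)[ok] >= 0))
  # off-wall voxels carry no measurement
  expect_true(all(is.na(thicknessMap(res)[gridLabels(run$grid) != WALL])))
})

test_that("ring thickness maps are nearly uniform at the phantom truth", {
  run2d <- cachedRun("circular_ring", 10)
  expect_lt(abs(run2d$stats$meanThickness - 1.5), 0.1)
  run3d <- cachedRun("half_spherical_shell", 10)
  expect_lt(abs(run3d$stats$meanThickness - 1.5), 0.15)
})

test_that("voxels on one streamline agree on the thickness", {
  run <- cachedRun("circular_ring", 20)
  grid <- run$grid
  h <- voxelSpacing(grid)[1]
  lab <- gridLabels(grid)
  R <- radiusArray(grid)
  tt <- thicknessMap(run$thickness)
  gamma <- run$thickness@diagnostics$gamma
  wallPos <- which(lab == WALL, arr.ind = TRUE)
  co <- lapply(1:2, function(k) {
    gridOrigin(grid)[k] + (seq_len(dim(lab)[k]) - 1) * h
  })
  set.seed(7)
  checked <- 0
  for (i in sample(nrow(wallPos), 40)) {
    v1 <- wallPos[i, ]
    p1 <- c(co[[1]][v1[1]], co[[2]][v1[2]])
    rho <- sqrt(sum(p1^2))
    # another lattice point near the same radial streamline
    p2 <- p1 * (rho + 0.5) / rho
    v2 <- round((p2 - gridOrigin(grid)) / h) + 1
    if (any(v2 < 1) || any(v2 > dim(lab))) next
    if (lab[v2[1], v2[2]] != WALL) next
    # only count pairs that are actually close to the same ray
    q2 <- c(co[[1]][v2[1]], co[[2]][v2[2]])
    ang <- acos(min(1, sum(p1 * q2) / (rho * sqrt(sum(q2^2)))))
    if (ang > 0.02) next
    checked <- checked + 1
    expect_lt(abs(tt[v1[1], v1[2]] - tt[v2[1], v2[2]]), 2 * gamma * h + 2 * h)
  }
  expect_gt(checked, 10)
})

test_that("error metrics: identities and the resolution trend", {
  g <- slabGrid(4L, 0.5, 4L)
  mk <- function(vals) {
    tt <- array(NA_real_, dim(gridLabels(g)))
    fl <- array(NA_integer_, dim(gridLabels(g)))
    wall <- gridLabels(g) == WALL
    tt[wall] <- vals
    fl[wall] <- 0L
    methods::new("ThicknessResult",
      thickness = tt, distOuter = tt, distLumen = tt * 0,
      flags = fl, grid = g, diagnostics = list()
    )
  }
  em0 <- errorMetrics(mk(1.5), 1.5)
  expect_equal(em0$bias, 0)
  expect_equal(em0$rmse, 0)
  em1 <- errorMetrics(mk(1.6), 1.5)
  expect_equal(em1$bias, 0.1)
  expect_equal(em1$rmse, 0.1)
  expect_equal(em1$mad, 0.1)

  sw <- cachedSweep("circular_ring", c(2, 5, 10))
  expect_true(all(diff(sw$rmse) <= 1e-12))
})

# At 0.2 mm pixels (5 px/mm) the circle/ellipse ordering is inside
# rasterization phase noise, so the comparison is made where the pixel size
# resolves it.
test_that("complex geometry errs at least as much as simple geometry", {
  ec <- errorMetrics(cachedRun("circular_ring", 10)$thickness, 1.5)
  ee <- errorMetrics(cachedRun("elliptical_ring", 10)$thickness, 1.5)
  expect_gte(ee$rmse, ec$rmse)
  expect_gte(ee$mad, ec$mad)
})

test_that("3D bias is no larger than 2D bias for the sphere/circle pair", {
  b2 <- abs(errorMetrics(cachedRun("circular_ring", 10)$thickness, 1.5)$bias)
  b3 <- abs(errorMetrics(cachedRun("half_spherical_shell", 10)$thickness,
                         1.5)$bias)
  gammaH <- 0.25 * 0.1
  expect_lte(b3, b2 + gammaH)
})

test_that("tracing is deterministic and order-independent", {
  g <- generatePhantom(phantomSpec("circular_ring", resolution = 5))
  u <- normalizeGradient(sobelGradient(solveLaplace(g)))
  r1 <- computeThickness(u)
  r2 <- computeThickness(u)
  expect_identical(thicknessMap(r1), thicknessMap(r2))
  # stride sampling fills skipped voxels from measured neighbours
  rs <- computeThickness(u, tracerControl(stride = 3L))
  wall <- gridLabels(g) == WALL
  expect_true(all(!is.na(thicknessMap(rs)[wall])))
  expect_lt(mean(abs(thicknessMap(rs)[wall] - thicknessMap(r1)[wall])), 0.2)
})
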