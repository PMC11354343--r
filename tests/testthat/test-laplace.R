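test_that("initialization: clamps at 0/1 and wall at the boundary average", {
  g <- generatePhantom(phantomSpec("circular_ring", resolution = 5))
  f <- initPotential(g)
  lab <- gridLabels(g)
  expect_true(all(potential(f)[lab == WALL] == 0.5))
  expect_true(all(potential(f)[lab == LUMEN] == 0))
  expect_true(all(potential(f)[lab == EXTERIOR] == 1))
  expect_false(converged(f))

  # one-voxel wall between the two regions still initializes at 0.5
  lab1 <- matrix(c(LUMEN, WALL, EXTERIOR), 3, 3)
  f1 <- initPotential(LabelGrid(lab1, spacing = 1))
  expect_equal(potential(f1)[2, 2], 0.5)
})

test_that("averaging kernels have the documented weights and sum to one", {
  k2 <- laplacianKernel(2)
  expect_equal(k2, matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0) / 4, 3, 3))
  k3 <- laplacianKernel(3)
  expect_equal(sum(k3), 1)
  expect_equal(sort(unique(as.vector(k3))), c(0, 1 / 6))
  expect_equal(sum(k3 != 0), 6)
  for (rank in 2:3) {
    ke <- laplacianKernel(rank, "extended")
    expect_equal(sum(ke), 1)
    expect_equal(ke[matrix(rep(2L, rank), 1)], 0)
  }
  expect_error(laplacianKernel(4), "rank")

  # any averaging variant leaves a constant field unchanged
  const <- array(0.37, c(5, 5))
  for (st in c("standard", "extended")) {
    out <- wallthick:::.stencilApply(const, laplacianKernel(2, st))
    expect_equal(out, const, tolerance = 1e-15)
  }
})

test_that("one Jacobi step is the neighbour average with re-clamped regions", {
  lab <- matrix(WALL, 3, 3)
  lab[1, 2] <- LUMEN       # value 0
  lab[3, 2] <- EXTERIOR    # value 1
  f <- initPotential(LabelGrid(lab, spacing = 1))
  f1 <- jacobiStep(f)
  # centre neighbours: 0 (lumen), 1 (exterior), 0.5, 0.5
  expect_equal(potential(f1)[2, 2], 0.25 * (0 + 1 + 0.5 + 0.5))
  expect_true(all(potential(f1)[gridLabels(labelGrid(f1)) == LUMEN] == 0))
  expect_equal(iterations(f1), 1L)
})

test_that("replicate padding at cap faces equals an explicit mirrored ghost layer", {
  g <- slabGrid(wallCols = 6L, h = 0.2, ny = 5L)
  f <- solveLaplace(g, solverControl(tol = 1e-8))
  stepped <- jacobiStep(f)
  # ghost-cell reference: mirror-pad across the y caps, convolve, crop
  phi <- potential(f)
  pad <- rbind(phi[1, c(1, seq_len(ncol(phi)), ncol(phi))],
               cbind(phi[, 1], phi, phi[, ncol(phi)]),
               phi[nrow(phi), c(1, seq_len(ncol(phi)), ncol(phi))])
  ref <- 0.25 * (pad[1:nrow(phi), 2:(ncol(phi) + 1)] +
                 pad[3:(nrow(phi) + 2), 2:(ncol(phi) + 1)] +
                 pad[2:(nrow(phi) + 1), 1:ncol(phi)] +
                 pad[2:(nrow(phi) + 1), 3:(ncol(phi) + 2)])
  lab <- gridLabels(g)
  ref[lab == LUMEN] <- 0
  ref[lab == EXTERIOR] <- 1
  expect_equal(potential(stepped), ref, tolerance = 1e-15)
  # mirror symmetry along the caps: cap rows equal the ring one inward
  expect_equal(potential(stepped)[, 1], potential(stepped)[, 2],
               tolerance = 1e-12)
})

test_that("energy is the RMS change over wall voxels", {
  g <- slabGrid(4L, 0.5, 4L)
  f <- initPotential(g)
  expect_equal(energyDelta(f, f), 0)
  f2 <- f
  f2@phi[gridLabels(g) == WALL] <- f2@phi[gridLabels(g) == WALL] + 1e-3
  expect_equal(energyDelta(f, f2), 1e-3)
  g2 <- slabGrid(5L, 0.5, 4L)
  expect_error(energyDelta(f, initPotential(g2)), "different grids")
})

test_that("slab potential is linear across the wall", {
  g <- slabGrid(wallCols = 15L, h = 0.1, ny = 8L, pad = 3L)
  f <- solveLaplace(g)
  expect_true(converged(f))
  phi <- potential(f)
  # clamped columns 3 and 19 (1-based) bracket the wall: linear profile
  ref <- (seq_len(nrow(phi)) - 3) / 16
  wallRows <- 4:18
  dev <- abs(sweep(phi[wallRows, , drop = FALSE], 1, ref[wallRows]))
  expect_lt(max(dev), 1e-4)
})

test_that("annulus and shell potentials approach the closed forms as resolution grows", {
  devFor <- function(res) {
    run <- cachedRun("circular_ring", res)
    phi <- potential(run$field)
    R <- radiusArray(run$grid)
    wall <- gridLabels(run$grid) == WALL
    max(abs(phi[wall] - log(R[wall] / 1.5) / log(2)))
  }
  d10 <- devFor(10); d20 <- devFor(20)
  expect_lt(d20, d10)
  # boundary placement error is below one voxel: |dev| <= max|phi'| * h
  expect_lt(d20, (1 / (1.5 * log(2))) * 0.05)

  f3 <- cachedShellSolve(10)
  R <- radiusArray(labelGrid(f3))
  wall <- gridLabels(labelGrid(f3)) == WALL
  ref <- (1 / 1.5 - 1 / R) / (1 / 1.5 - 1 / 3)
  dev3 <- max(abs(potential(f3)[wall] - ref[wall]))
  expect_lt(dev3, (1 / 1.5^2) / (1 / 1.5 - 1 / 3) * 0.1)
})

test_that("maximum principle and energy monotonicity hold along the solve", {
  run <- cachedRun("circular_ring", 10)
  phi <- potential(run$field)
  lab <- gridLabels(run$grid)
  expect_equal(min(phi), 0)
  expect_equal(max(phi), 1)
  expect_true(all(phi[lab == WALL] > 0 & phi[lab == WALL] < 1))
  tr <- energyTrace(run$field)
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("the converged field is a fixed point of further iteration", {
  g <- generatePhantom(phantomSpec("circular_ring", resolution = 5))
  f1 <- solveLaplace(g, solverControl(tol = 1e-6))
  f2 <- f1
  for (i in 1:50) f2 <- jacobiStep(f2)
  # residual drift is bounded by the geometric tail of the iteration
  expect_lt(energyDelta(f1, f2), 1e-4)
})

test_that("solutions inherit lattice symmetries of symmetric inputs", {
  f <- cachedRun("circular_ring", 5)$field
  phi <- potential(f)
  expect_identical(phi, phi[rev(seq_len(nrow(phi))), ])
  expect_identical(phi, phi[, rev(seq_len(ncol(phi)))])
  expect_identical(phi, t(phi))
})

test_that("shift and fft convolution backends agree on the solved field", {
  g <- generatePhantom(phantomSpec("circular_ring", resolution = 5))
  fS <- solveLaplace(g, solverControl(backend = "shift"))
  fF <- solveLaplace(g, solverControl(backend = "fft"))
  expect_equal(iterations(fS), iterations(fF))
  wall <- gridLabels(g) == WALL
  rms <- sqrt(mean((potential(fS)[wall] - potential(fF)[wall])^2))
  expect_lt(rms, 1e-10)
})

test_that("non-convergence is a warning carrying diagnostics, not an error", {
  g <- generatePhantom(phantomSpec("circular_ring", resolution = 5))
  expect_warning(f <- solveLaplace(g, solverControl(maxIters = 5)), "did not reach")
  expect_false(converged(f))
  expect_equal(iterations(f), 5L)
})
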