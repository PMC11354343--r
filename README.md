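# wallthick

Voxel-wise vessel wall thickness from segmentation masks, by the Laplacian
(equipotential–streamline) method, in 2D and 3D.

## The problem

Vessel wall thickness is a standard imaging biomarker of cardiovascular
disease, but most measurement pipelines are 2D: they extract cross-sectional
slices (ideally perpendicular to a lumen centerline), measure on the slice,
and report values only along the lumen contour. On tortuous or branching
arteries the slice choice drives the answer, and thickness variation across
the wall volume is lost. `wallthick` treats the measurement as the 3D
problem it is: given a labelled image (lumen / wall / exterior), it returns
a thickness value at **every wall voxel**, plus per-voxel distance-to-lumen
and distance-to-outer-wall maps, with no centerlines or slices involved.
The same code path handles 2D images (e.g. digitized histology sections).

## The method

Assign a harmonic potential to the wall by solving Laplace's equation with
Dirichlet boundary values on the two surfaces,

```
∇²φ = 0  in the wall,   φ|lumen = 0,   φ|exterior = 1,
```

with Neumann conditions (∇φ·n̂ = 0) on faces where the vessel is cut by the
image boundary. The solver is Jacobi iteration written as a convolution:
each wall voxel is replaced by the average of its face neighbours (the
five-/seven-point stencil kernel), the boundary regions are re-clamped every
step, and convergence is monitored by the energy E = ‖φ⁽ⁱ⁺¹⁾ − φ⁽ⁱ⁾‖ (RMS
per wall voxel). From every wall voxel, two streamlines of the normalized
gradient field n̂ = ∇φ/‖∇φ‖ (Sobel–Feldman gradients, multilinear
interpolation off-lattice) are integrated with Euler steps γ = h/4: the
positive path reaches the outer wall after length T⁺, the negative path
reaches the lumen after length T⁻, and the thickness is

```
T = T⁺ + T⁻.
```

ROI morphometrics (area, normalized index = ROI area / (lumen + wall area),
mean ± SD thickness and distance-to-lumen per region) reproduce the usual
histology tables. Digital phantom generators (circular/elliptical rings,
half-spherical/half-ellipsoid shells, bent pipe — all with exactly uniform
wall thickness by construction) support validation at any resolution.

See `vignettes/laplacian-wall-thickness.Rmd` for the discretization details
and numerical choices.

## Worked example

A 1.5 mm-thick circular ring phantom (inner radius 1.5 mm) rasterized at
10 px/mm, measured end to end:

```r
library(wallthick)
spec <- phantomSpec("circular_ring", resolution = 10)   # h = 0.1 mm
run  <- runPipeline(spec, quiet = TRUE)
run$stats
#>  wallVoxels fractionOk meanThickness sdThickness meanDistLumen iterations converged
#>        2112          1      1.517045  0.03914549     0.8402462        680      TRUE
errorMetrics(run$thickness, truth = 1.5)
#> $bias 0.017   $rmse 0.0427   $mad 0.0364   $n 2112
```

The mean measured thickness is 1.517 mm against a ground truth of 1.5 mm —
within a fifth of a pixel — with every streamline trace terminating
correctly (`fractionOk = 1`). `thicknessMap(run$thickness)` is the
per-voxel map (mm, `NA` off the wall); `distToLumenMap()` and
`distToOuterMap()` give the two path-length maps, and
`resolutionSweep("circular_ring", c(2, 5, 10, 20, 50))` tabulates how bias
and RMSE shrink as resolution grows.

For real masks: `readLabelImage("mask.nii.gz", mapping = c(exterior = 0,
lumen = 1, wall = 2))`, optionally `resampleIsotropic()` and
`upsampleAndSmooth()` (×3 upsampling with Gaussian indicator smoothing, the
standard accuracy enhancement before measurement), then the same
`runPipeline()`. A thin CLI wrapping these steps is installed at
`inst/cli/wallthick.R` (subcommands `phantom`, `run`, `sweep`).

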