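---
title: "Measuring vessel wall thickness with the Laplacian equipotential method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vessel wall thickness with the Laplacian equipotential method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallthick)
```

## The measurement problem

The thickness of a vessel wall is well defined only where the two bounding
surfaces — the lumen–wall interface and the wall–exterior interface — are
parallel. Real arterial walls are not parallel-sided: cross-sections are
eccentric, plaque thickens the wall locally, and in 3D the vessel bends and
branches. Ruler-style definitions (nearest point on the opposite surface,
normal-ray casting) become ambiguous or inconsistent exactly where the
measurement is most interesting.

The Laplacian (equipotential) method resolves the ambiguity by filling the
wall with a harmonic potential field: solve

$$\nabla^2 \phi = 0 \quad \text{in the wall}, \qquad
  \phi\big|_{\text{lumen}} = 0, \quad \phi\big|_{\text{exterior}} = 1,$$

optionally with Neumann conditions $\nabla\phi\cdot\hat n = 0$ on artificial
end caps where a vessel was cut by the image boundary. The level sets of
$\phi$ form a family of nested, non-crossing sublayers interpolating between
the two surfaces. From any point in the wall, following the normalized
gradient field $\hat n = \nabla\phi / \lVert\nabla\phi\rVert$ *outward*
until leaving the wall gives a path of length $T^+$ (the distance to the
outer wall), following $-\hat n$ *inward* gives $T^-$ (the distance to the
lumen), and

$$T = T^+ + T^-$$

is the wall thickness at that point. The definition is self-consistent
(points on one streamline agree on $T$), works identically in 2D and 3D, and
yields a thickness value at *every* wall voxel rather than only on the lumen
contour.

## Discretization

`wallthick` operates on label lattices (`LabelGrid`): integer images with
codes `EXTERIOR = 0`, `LUMEN = 1`, `WALL = 2`, plus the physical voxel
spacing `h` (mm), the origin, and the set of cap faces.

**Solver.** The five-point (2D) / seven-point (3D) finite-difference
Laplacian leads to the Jacobi fixed-point update: each wall voxel is
replaced by the average of its face neighbours, which is a convolution with
the kernel $\tfrac14\,[0\,1\,0;\,1\,0\,1;\,0\,1\,0]$ (2D) or its 1/6
face-neighbour 3D analogue (`laplacianKernel()`). After every convolution
the Dirichlet regions are re-clamped: all lumen voxels to 0, all exterior
voxels to 1. Lattice borders use replicate padding, which realizes the
zero-normal-gradient condition on cap faces; all non-cap borders are
exterior voxels, where the clamp makes the padding choice irrelevant.
An `extended` kernel variant (the `[1,4,1]` outer-product family with the
centre zeroed: 9 neighbours in 2D, 26 in 3D) is available through
`solverControl(stencil =)`; it damps high-frequency staircase modes faster
per iteration at slightly more work, and converges to the same field.

Convergence is monitored by the energy
$E^{(i+1)} = \lVert \phi^{(i+1)} - \phi^{(i)} \rVert$, implemented as the
RMS per-wall-voxel change so that the default tolerance `tol = 1e-6` means
the same thing at every resolution. $E$ is non-increasing for this
iteration (the Jacobi matrix is symmetric with spectral radius below one),
which the test suite checks numerically. Non-convergence within `maxIters`
is a warning, not an error, so diagnostics stay inspectable on difficult
inputs.

Two convolution backends are provided and cross-checked to below
$10^{-10}$ RMS: the default clamped-index shifted-sum (`"shift"`) and a
DFT-based path (`"fft"`). Opposite stencil offsets are summed pairwise
before accumulation, so mirror images and transposed inputs give
bit-identical solutions — floating-point addition is commutative even
though it is not associative.

**Boundary placement.** Clamping whole regions is the simplest stable
realization of the Dirichlet conditions, and it is what the convolutional
formulation calls for. Its known cost is that the discrete 0/1 level sits
*at the outermost clamped voxel centres*, i.e. within one voxel inside/
outside the true interface, so the potential near a curved boundary carries
an $O(h)$ placement bias on top of $O(h)$ staircase jitter. On the annulus
phantom at 20 px/mm the worst-case deviation from the closed-form potential
$\ln(r/r_0)/\ln(r_1/r_0)$ is about 0.027, and fitting effective radii shows
it is almost entirely boundary placement. The bias shrinks linearly with
resolution and cancels to first order in the *thickness* (both path ends
shift the same way), which is why thickness accuracy is much better than
potential accuracy at matched resolution.

**Gradient.** Gradients are computed with the Sobel–Feldman operator:
smoothing `[1,2,1]` across the non-derivative axes and the spacing-2
central difference `[-1,0,1]` along the derivative axis, normalized (1/8 in
2D, 1/32 in 3D) so a unit-slope ramp yields a unit gradient; the operator is
exact on quadratics along the derivative axis. Normalization to unit
vectors flags voxels with magnitude below `eps = 1e-8` as invalid rather
than erroring: deep clamped regions are legitimately flat. During tracing,
directions at off-lattice points are obtained by interpolating the *unit*
field and renormalizing — interpolating raw gradients instead would let the
large-magnitude response near the clamps dominate the direction close to
the boundaries. One caveat documented by the tests: wall voxels immediately
adjacent to a clamped region see the staircase edge of the 0/1 plateau, so
their directions can tilt a few degrees off the ideal; on the annulus
phantom the interior wall voxels are radial to within 2 degrees at the 99%
level, while the first/last layer is noisier.

**Tracer.** Streamlines are integrated with explicit Euler steps of
$\gamma = h/4$ (in lattice units, `gamma = 0.25`), per the guidance that
the step stay below one voxel. A path terminates when the *nearest voxel*
at the current position is no longer wall; there is no sub-voxel boundary
refinement, so each path end carries a quantization residual of at most
$\gamma h$, which the step-size choice keeps well below voxel scale. Path
length is (steps $\times\ \gamma \times h$) mm, and $T = T^+ + T^-$ holds
identically by construction. Tracing is per-voxel independent: results do
not depend on evaluation order, and repeated runs are bit-identical.
Failure modes are recorded per voxel (`invalid_gradient`, `max_steps`,
`out_of_bounds`); by default failed voxels inherit values from their
nearest successful neighbour but keep their failure flag, so they can never
silently contaminate statistics. If more than 10% of traces fail, a warning
points at the usual causes (wall under-resolved, boundaries not separated).
For very large grids, `tracerControl(stride =)` measures a regular subset
and fills the rest from nearest measured voxels; it is off by default
because exactness is preferred to speed.

## Digital phantoms

`generatePhantom()` builds the validation geometries with analytically known
uniform thickness `d`: a circular ring (inner radius 1.5 mm), an elliptical
ring (inner semi-axes 1.5/1.0 mm), a half-spherical shell (inner radius
1.5 mm), a half-ellipsoid shell (semi-axes 2.0/1.5/1.0 mm), and a bent pipe
(tube radius 1.5 mm around a quarter-circle axis of radius 4.5 mm), all
with d = 1.5 mm by default. Classification is at voxel centres: lumen
inside the inner surface, wall where the Euclidean distance to the inner
surface is in $(0, d]$. The outer boundary is therefore the *true offset*
of the inner surface — for the ellipse/ellipsoid this is deliberately not a
scaled ellipse, which would not have uniform thickness. Distances are
evaluated exactly (closed form for circle/sphere/torus; vectorized
root-finding on the standard point-to-ellipsoid equation, accurate to
~1e-12 mm), so rasterization error is confined to the voxel-centre
classification itself. Half shells are clipped at the equatorial plane and
the pipe at its two quarter-arc planes; the clip planes coincide with
lattice faces and are recorded as Neumann caps. Non-cap faces get a
4-voxel exterior margin. Lattices are centred so that every analytic mirror
symmetry is an exact lattice symmetry.

A warning is emitted when `d/h <= 3` (three or fewer voxel layers across
the wall): below that, path quantization and boundary bias dominate and
measurements are unreliable, matching the error growth seen at the coarsest
validation resolutions.

The phantoms emulate clean, noise-free segmentations with exactly known
geometry. They do not emulate segmentation errors, anisotropic acquisition,
partial-volume mislabelling, or touching vessels; passing phantom tests
therefore validates the measurement operator, not the robustness of any
upstream segmentation.

## Preprocessing real masks

Measurement assumes isotropic voxels. `resampleIsotropic()` brings
anisotropic grids to the *minimum* input spacing (always upsampling, never
destroying thin walls), resampling each label's indicator independently and
relabelling by argmax with tie precedence `WALL > LUMEN > EXTERIOR`, so
ties never erode the measurement domain. `upsampleAndSmooth()` implements
the standard accuracy-enhancement for coarse in vivo masks: split each
voxel by an integer factor (default 3), Gaussian-smooth the label
indicators (default sigma 0.5 upsampled voxels — the smoothing width is not
prescribed anywhere authoritative, so a conservative half-voxel was fixed
once), and relabel by argmax. Smoothing on indicators with hard argmax
relabelling keeps a crisp boundary for the Dirichlet clamps. If smoothing
ever connects lumen to exterior (a breached wall), the operation fails
loudly, naming a breach location.

## ROI morphometrics

`roiArea()`, `normalizedIndex()`, `roiThicknessStats()` and `roiReport()`
reproduce the standard histology-style table: area (voxel count times
$h^{\text{rank}}$), normalized index (ROI area over total vessel area,
where total = lumen + wall, so the lumen and outer-wall indices of a sample
sum to one), and mean ± SD of thickness and distance-to-lumen over the ROI.
Statistics are voxel-weighted over ROI ∩ wall ∩ ok-traces; standard
deviations are population (divide-by-N) moments — at histology ROI sizes
the sample/population distinction is below reported precision.

## Problem sizes and numerical defaults

The shipped validation runs use 2D resolutions up to 50 px/mm and 3D
resolutions up to 10 vx/mm (lattices up to roughly $80^2\times70$,
i.e. ~0.5M voxels); higher 3D resolutions are excluded as computationally
disproportionate for routine validation, consistent with the published
practice for these phantoms. Defaults chosen once and used everywhere:

| parameter | default | meaning |
|---|---|---|
| `tol` | 1e-6 | RMS per-wall-voxel change per iteration |
| `maxIters` | 20000 | Jacobi cap |
| `checkEvery` | 10 | energy evaluation period (iterations) |
| `gamma` | 0.25 | Euler step, lattice units (h/4) |
| `eps` | 1e-8 | gradient magnitude floor |
| `upsampleFactor` | 3 | mask upsampling before measurement |
| `gaussianSigma` | 0.5 | indicator smoothing, upsampled voxels |
| `margin` | 4 | phantom exterior padding, voxels |

## Worked example

```{r example, eval = FALSE}
spec <- phantomSpec("circular_ring", resolution = 10)   # h = 0.1 mm
run <- runPipeline(spec, quiet = TRUE)
run$stats
errorMetrics(run$thickness, truth = 1.5)
```

At 10 px/mm the mean measured thickness of the 1.5 mm ring is 1.517 mm with
SD 0.039 mm; at 50 px/mm the mean is within 0.02 mm of truth. The
`resolutionSweep()` helper tabulates bias/RMSE against resolution for any
phantom, reproducing the error-versus-resolution validation curves.

## Known limitations

* Thickness is only meaningful where the segmentation separates the two
  boundaries; touching vessels (e.g. at a carotid flow divider) must be
  separated in the mask first.
* The region-clamped Dirichlet condition carries an $O(h)$ boundary
  placement bias in the *potential*; thickness is far less affected (the
  bias largely cancels between the two path ends) but very coarse walls
  (three voxel layers or fewer) are unreliable.
* Directions in the first/last wall layer are a few degrees noisier than in
  the wall interior (staircase edge of the clamped plateaus).
* Path termination is at nearest-voxel resolution; residuals are bounded by
  $\gamma h$ per path end.
* No segmentation, registration, centerline extraction, or surface-mesh
  rendering is provided: label images in, voxel maps and tables out.
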