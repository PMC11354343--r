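Package: wallthick
Title: Voxel-Wise Vessel Wall Thickness by the Laplacian Equipotential Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures vessel wall thickness on 2D and 3D segmentation masks by
    solving Laplace's equation between the lumen and outer-wall boundaries with
    convolutional Jacobi iteration, then tracing bidirectional streamlines along
    the normalized potential gradient. Produces per-voxel maps of thickness,
    distance to lumen, and distance to outer wall, together with region-of-interest
    morphometrics (area, normalized index, thickness statistics). Includes digital
    phantom generators (rings, shells, bent pipes) with analytically known uniform
    thickness for validation, isotropic resampling and upsample-and-smooth
    preprocessing for anisotropic or coarse masks, and NIfTI/PNG/TIFF input and
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils-lattice.R'
    'AllClasses.R'
    'AllGenerics.R'
    'labelgrid.R'
    'preprocess.R'
    'phantoms.R'
    'laplace.R'
    'gradient.R'
    'thickness.R'
    'roi.R'
    'io.R'
    'pipeline.R'
    'wallthick-package.R'
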