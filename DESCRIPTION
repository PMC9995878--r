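Package: nervedti
Title: Diffusion Tensor Analysis of Peripheral Nerve Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diffusion tensor imaging (DTI) of ex vivo peripheral
    nerve at microscopy resolution. Simulates multi-compartment median-nerve
    diffusion-weighted phantoms with Rician noise, fits diffusion tensors by
    log-linear least squares from voxelwise or region-averaged signals,
    computes fractional anisotropy, mean diffusivity and the axial-to-radial
    diffusivity ratio per anatomical compartment (fascicles, perineurium,
    interfascicular epineurium), derives fascicular morphometry
    (cross-sectional areas and compartment ratios), runs the associated
    statistics (one-way intraclass correlation, coefficients of variation,
    slice-wise trend regression, per-sample slope testing), and exports
    deterministic first-eigenvector streamlines and diffusion-ellipsoid
    glyph fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm
Config/testthat/edition: 3
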