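Package: cedflow
Title: Convection-Enhanced Delivery Simulation on Diffusion-MRI-Derived
    Brain Microstructure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds voxel-wise anisotropic diffusivity and hydraulic
    permeability tensor fields for brain tissue from diffusion tensor
    imaging (DTI) and neurite orientation dispersion and density imaging
    (NODDI) maps, including microstructure-based permeability laws
    obtained by homogenising creeping flow through triangular fibre
    lattices; simulates intraparenchymal drug infusion
    (convection-enhanced delivery) as steady Darcy flow plus transient
    advection-diffusion-loss transport on the voxel grid; and quantifies
    infusion outcomes with shape and concentration metrics (thresholded
    infusion volume, RMSD, principal direction, penetration length,
    overlap).  A synthetic phantom generator provides DTI/NODDI-like
    inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
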