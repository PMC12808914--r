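Package: porolith
Title: Quantitative Characterization of 3D-Printed Porous Polymer Monoliths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hierarchically porous, 3D-printed
    molecularly imprinted polymer (MIP) monoliths used for small-molecule
    enrichment. Implements batch-binding quantitation (adsorption capacity,
    imprinting factor, enrichment factor), pseudo-first/second-order uptake
    kinetics and Crank's finite-bath plane-sheet diffusion model, parametric
    lattice macrogeometry generation with voxelization and STL export,
    mercury-intrusion Washburn inversion and pycnometry-based total porosity,
    voxel tomography metrics (porosity, pore connectivity, local thickness),
    Oliver-Pharr nanoindentation analysis, and midpoint glass-transition
    extraction from modulated DSC traces. Seeded synthetic-data generators
    emulate every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    signal,
    jsonlite,
    EBImage,
    tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'diffusion.R'
    'kinetics.R'
    'lattice.R'
    'mech_thermal.R'
    'pipeline.R'
    'porolith-package.R'
    'porosimetry.R'
    'quantitation.R'
    'synthetic.R'
    'tomography.R'
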