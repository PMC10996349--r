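Package: tdcsflow
Title: Multi-Scale Electroosmotic Water Flux Modelling for Transcranial
    Direct Current Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Couples transcranial direct current stimulation (tDCS) electric
    fields to electroosmotic water flux across the blood-brain barrier (BBB)
    and predicts net interstitial fluid exchange per brain voxel. Implements
    the equilibrium double-layer potential and electroosmotic velocity
    profile in a slit-like tight junction with overlapping double layers,
    TEER-based conversion of transendothelial resistance to wall and
    tight-junction conductivities, a reduced-order series-parallel
    conductance model of the BBB ultrastructure, a seeded synthetic capillary
    network generator with a finite-difference Laplace solver for wall
    current densities under closed or open vascular boundary conditions, and
    the flux pipeline that converts wall current density to volumetric water
    flux and voxelwise exchange maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
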