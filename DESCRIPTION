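Package: aorta4d
Title: Aortic Hemodynamics from 4D Flow MRI Velocity Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved three-directional
    phase-contrast (4D flow) magnetic resonance velocity data of the
    thoracic aorta. Provides synthetic pulsatile tube-flow phantoms with
    analytic ground truth, phase-contrast preprocessing (noise masking,
    velocity anti-aliasing, eddy-current offset correction), PC-MRA
    computation and lumen segmentation, surface and centerline
    extraction, vertex-wise three-dimensional wall shear stress with
    systolic averaging and a ten-segment regional analysis, quantitative
    helix and vortex flow grading from tracer winding angles, and the
    accompanying morphometric and agreement statistics (body surface
    area, diameter Z-scores, normality-gated comparisons, Cohen's kappa,
    Bland-Altman limits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
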