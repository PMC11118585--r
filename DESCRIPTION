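Package: vorquant
Title: Quantification of Vestibulo-Ocular Reflex Ontogeny from Tilt-Step Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for developmental studies of torsional gaze
    stabilization in larval zebrafish. Builds trapezoidal tilt-step stimulus
    profiles and protocols, converts torsional eye-position traces into
    vestibulo-ocular reflex gains (cubic-spline resampling, zero-phase
    Butterworth velocity estimation, saccade exclusion, cycle averaging),
    scores tilt-evoked calcium traces into dF/F responses, directionality
    indices, sensitivity slopes and longitudinally paired per-neuron
    differences, quantifies neuromuscular-junction labeling in extraocular
    muscle images (% area labeled, particle statistics), and runs the
    associated group-comparison statistics. Includes synthetic-data
    generators with ground truth for every modality so the whole pipeline is
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    mgcv,
    emmeans,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
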