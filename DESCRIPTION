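Package: spinescan
Title: Spatial Spine-Curve Determination from Back-Surface Laser Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the spatial (3D) thoracic-lumbar spine curve from an
    ordered point-cloud scan of a human back, as acquired by laser-triangulation
    profilometry. The automatic curve is tracked along the posterior median
    furrow via transverse surface-curvature extrema with sub-pixel refinement;
    the manual reference curve is extracted from a marker line drawn on the
    skin, via smoothed intensity minima. Detected image-space curves are lifted
    to 3D, smoothed with least-squares cubic splines, projected to the frontal
    and sagittal planes, and compared by per-plane RMSD, with cohort-summary and
    intra-/inter-operator repeatability statistics. Includes a parametric
    synthetic back-surface generator with known ground truth for validation,
    readers/writers for PLY and a plain grid-text scan format, ggplot2
    visualisations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
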