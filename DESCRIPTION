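Package: optomotor
Title: Bilateral Optic-Flow Course-Control Analysis for Walking Flies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for closed-loop optomotor experiments with freely
    walking flies and for the lobula-plate circuitry thought to drive them.
    Provides a synthetic closed-loop walking simulator with known ground truth,
    silhouette tracking (ellipse fit plus two-threshold Otsu heading
    disambiguation), kinematics preprocessing with trial exclusion rules,
    stationary-wavelet (bior2.6) saccade detection with smooth/saccadic turning
    decomposition, windowed path-straightness, the full-field versus summed
    unilateral linearity test with group statistics, patch-clamp analyses
    (rolling-baseline subtraction, scanning-bar receptive-field vector-field
    reconstruction, power-band fractions, flash and grating tuning), and a
    bilateral HS-H2 rate-network model with ohmic gap-junction coupling and a
    rotation/translation Discrimination Index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
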