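Package: sensorlayout
Title: Computational Design of Multi-Modal Electro-Physiological Sensor Layouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computationally designing electrode layouts for
    multi-modal electro-physiological sensing (surface EMG, electrodermal
    activity, and ECG) on the anterior forearm. Provides an integrated
    predictive cost model built from published placement guidance (electrode
    orientation and inter-electrode distance curves for EMG, sweat-gland
    coverage for EDA, keypoint signal-to-noise scores for ECG, and a convex
    hull area term), a simulated-annealing optimizer for geometric packing of
    electrodes under anatomical and spacing constraints, a bounding-box sweep
    protocol that produces area-optimized and quality-optimized designs, and
    JSON/SVG export of the resulting layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
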