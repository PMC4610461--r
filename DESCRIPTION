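Package: signcoded
Title: Component-Level Recognition of Coded Sign Gestures from sEMG and
    Accelerometer Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising coded sign gestures from synchronised
    multichannel surface electromyography (sEMG) and triaxial accelerometer
    (ACC) recordings. Continuous recordings are segmented into active gestures
    by an overlapped sliding-average energy detector, each segment is described
    by palm-orientation, hand-movement and hand-shape features, and the three
    components are classified (per-class Gaussian discriminant, slope-constrained
    dynamic time warping, and left-to-right Gaussian-mixture hidden Markov
    models trained by Baum-Welch) before being fused into gesture labels and
    decoded into character identifiers through a code table. A built-in
    synthetic signal simulator with ground-truth annotations makes the whole
    pipeline testable end to end without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
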