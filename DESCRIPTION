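Package: caprax
Title: Behaviour Classification from Collar-Mounted Accelerometry and
    Magnetometry in Caprids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying the behaviour of goats, ibex and related
    Caprids from collar-mounted tri-axial accelerometer and magnetometer
    streams. Implements windowed feature derivation (static/dynamic
    decomposition, VeDBA, posture angles, oscillation amplitudes,
    magnetometry summaries), random-forest behaviour models with
    correlation pruning and recursive feature elimination, random and
    individual-level train/validation splits, class balancing by
    down-sampling, sampling-frequency sweeps, terrain-slope
    classification for locomotion, and cross-species model transfer.
    Includes a labelled synthetic biologging simulator so the full
    workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
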