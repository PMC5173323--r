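Package: trackmotility
Title: Motility Analysis of Intravital Cell Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-track and per-cohort motility statistics for time-lapse cell
    trajectories exported from commercial tracking software: instantaneous and
    mean velocity, arrest coefficient, confinement ratio, immotile
    classification, and cohort mean-displacement-versus-square-root-of-time
    curves with the linear-fit random-walk criterion. Includes a synthetic
    track simulator (random-walk, confined, directed, and stop-and-go motion
    models) with presets calibrated to published intravital T-cell motility
    regimes, spatial density and phenotype-fraction quantification of labeled
    cell point patterns with a peri-tumoral ring profile, nonparametric group
    comparison statistics (Kruskal-Wallis with Dunn's post-hoc tests), and
    closed-form bench calculations for cytotoxicity and caliper tumor volume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
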