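Package: neuroband
Title: Individually Anchored EEG Alpha Band Ratios, White-Matter
    Hyperintensity Segmentation and Cortical Thickness Morphometry
Version: 0.1.0
Authors@R:
    person("TOMC", "Pipeline Maintainers", email = "neuroband@example.org",
           role = c("aut", "cre"))
Description: Computes the alpha3/alpha2 resting-EEG power ratio from
    individually anchored frequency bands (theta/alpha transition frequency
    and individual alpha frequency detected on a channel-collapsed Welch
    spectrum), stratifies cohorts into low/middle/high ratio groups,
    segments white-matter hyperintensities from FLAIR-like volumes by
    Gaussian intensity modelling, and runs vertex-wise cortical-thickness
    group comparisons and thickness-memory correlation maps with
    cluster-extent thresholding.  Seed-deterministic synthetic generators
    for EEG, lesion volumes and thickness cohorts make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
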