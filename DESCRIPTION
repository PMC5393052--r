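Package: telostorm
Title: STORM Telomere Cluster Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule localization microscopy
    (STORM) measurements of telomere size and chromatin compaction. Covers
    simulation of ground-truthed localization datasets with fluorophore
    blinking, stage drift and fiducial beads; a simplified maximum-likelihood
    localization stage for raw frame stacks; fiducial-based drift correction;
    quality filtering and blink merging; density-based spatial clustering of
    localizations into telomere candidates; registration of localizations to
    wide-field reference images and DNA-damage-marker overlap classification;
    per-cluster morphometrics (radius of gyration, convex hull); and
    condition-level statistics including the chromatin density-ratio and
    compaction-factor estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    igraph,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
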