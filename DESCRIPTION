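Package: shellmea
Title: Spike Detection and Group Comparison for Multielectrode Array
    Recordings of Brain Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for extracellular multielectrode array (MEA)
    recordings of brain organoids, contrasting 3D shell electrodes wrapped
    around the organoid surface with conventional 2D planar electrodes.
    Provides robust MAD-based noise estimation, threshold spike detection
    with window isolation, cross-electrode spike de-duplication by temporal
    merging, one-to-one matching of spikes detected in common by two
    electrode groups, Mann-Kendall trend statistics with tie correction,
    rank-sum and label permutation inference, and a synthetic multi-channel
    recording generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
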