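Package: runstop
Title: Segmentation of Bacterial Swimming Tracks into Run and Stop Phases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the automated analysis of bacterial tracking data.
    Segments two-dimensional centroid trajectories into running and
    stopping (reorientation) phases using a two-state hidden Markov model
    whose observation densities are estimated empirically, by kernel
    density estimation, from tracks of non-motile and non-chemotactic
    mutant strains. Includes a censoring protocol that removes spurious,
    non-motile and anomalously tortuous tracks; a heuristic threshold
    classifier and a minimum-duration post-processing smoother for
    comparison; a run-and-stop velocity-jump simulator with additive
    Gaussian observation noise for validating the methods against a known
    ground truth; centroid detection from greyscale image stacks; and
    evaluation utilities (event-level false positive/negative rates,
    stopwise reorientation angles, and a two-sample Kuiper test).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
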