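Package: commdynet
Title: Dynamic Community Analysis of Cortical Fluorescence Imaging Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for inferring dynamic community structure in cortical
    fluorescence imaging movies. Builds sliding-window, thresholded
    pixel-correlation temporal networks from image stacks, detects static
    communities per snapshot by Louvain modularity optimization, links them
    over time by social-cost minimization (switching, visiting and absence
    costs), and computes interpretable per-pixel community metrics
    (observation, switching, visiting, absence rates, stay lengths, homing,
    group and community sizes, community time span). Includes a synthetic
    movie generator with planted, possibly time-varying pixel communities,
    signal characterization (SNR, dominant frequency), degree maps, group
    statistics with Holm-Bonferroni correction, a random-forest dose
    classifier with leave-one-out validation, and an edge-dropping network
    degradation experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    png,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
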