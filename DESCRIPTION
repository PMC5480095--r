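Package: neurohcs
Title: High-Content Morphofunctional Profiling of Neuronal Network Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for high-content screening of
    primary neuronal cultures. Provides segmentation-based morphology readouts
    (cytotoxicity from propidium-iodide positive nuclei, neurite density from a
    dual-mask network segmentation, synaptic puncta density, tubulin intensity
    ratios and Pearson colocalization, fibrillar-Tau particle load), calcium
    burst-synchrony metrics with glutamate-based neuron gating, EB3 comet
    velocimetry from kymographs, per-well aggregation, and the nonparametric
    statistics layer (Shapiro-Wilk, Kruskal-Wallis, Steel many-to-one and Dunn
    all-pairs rank tests). A synthetic-data generator renders every input the
    pipeline consumes with known ground truth, so all stages are testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
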