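Package: imflow
Title: On-Chip Multi-Imaging Flow Cytometry Simulation and Morphometric
    Analysis for Label-Free Cell-Cluster Detection
Version: 0.1.0
Authors@R:
    person("Imflow", "Developers", email = "imflow@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing paired bright-field and
    fluorescence frame streams from an on-chip imaging flow cytometer.
    Provides a synthetic frame generator with exact ground truth
    (hydrodynamically focused debris, leukocyte-like cells, large single
    cells and multi-cell clusters with stained nuclei), extraction of
    morphometric imaging biomarkers (cross-sectional area, Crofton
    perimeter, aspect ratio, watershed cell count, nucleus count and
    nucleus area via bright-field/fluorescence co-registration),
    rule-based debris/cell/cluster classification, a virtual sort-trigger
    and outlet-routing model, and size-distribution analytics (binned
    histograms, peak detection, band fractions, total-variation shift
    statistics, time-course summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    png,
    digest,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
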