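Package: chromofold
Title: Local Chromatin Fiber Folding: Mesoscale Monte Carlo Simulation and
    Micro-C Contact Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying local chromatin fiber folding at nucleosome
    resolution. Implements a coarse-grained (mesoscale) chromatin fiber model
    with nucleosome cores, linker DNA, flexible histone tails and linker
    histones, sampled by Metropolis/configurational-bias Monte Carlo with five
    tailored moves; fiber compaction analytics (sedimentation coefficient,
    radius of gyration, alpha-shape volume, packing ratio, density-based
    nucleosome clustering, internucleosome contact maps and tail-interaction
    matrices); a Micro-C style contact pipeline (pair orientation filtering,
    multi-resolution binning, contact-probability decay curves, long/short
    odds ratios, anchor pileups, stratum-adjusted correlation); a morphological
    erosion estimator of fiber diameter from segmented 3-D volumes; and
    synthetic-data generators for every input so the whole workflow runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    RNifti,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
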