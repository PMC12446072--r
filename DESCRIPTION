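Package: msiunify
Title: Unified Processing of Multi-Acquisition Mass Spectrometry Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates many mass spectrometry imaging (MSI) acquisitions into
    one analyzable dataset. Provides count-based adaptive peak calling on
    detection-frequency histograms, cross-acquisition peak matching posed as a
    minimum-cost network-flow problem, and removal of factorized
    acquisition-by-compound batch effects from bimodal log-intensity
    distributions via maximum a posteriori estimation of a hierarchical
    Bayesian mixture model. Includes image-quality metrics, a stratified
    permutation test for spatial structure based on Moran's I, simulators for
    mass-shifted spectra, multi-section peak lists and batch-affected intensity
    panels, and the benchmark metrics needed to evaluate every stage without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stats,
    utils,
    xml2,
    yaml,
    generics,
    mclust,
    methods,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
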