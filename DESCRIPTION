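Package: evoadapt
Title: Adaptation Dynamics and Diminishing-Return Epistasis in
    Serial-Transfer Evolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-throughput adaptive laboratory
    evolution experiments in which microbial colony populations are
    serially passaged on solid media and phenotyped by population-size
    growth curves. Provides growth-curve processing (median despiking,
    Gaussian smoothing, sliding-window estimation of the maximum specific
    growth rate and doubling time), spatial plate normalization against
    interleaved non-evolving reference colonies, LOESS adaptation
    trajectories with milestone extraction, regression of adaptation on
    preadaptation fitness with FDR outlier screening, and quantification
    of diminishing-return (global) epistasis from reconstructed-mutation
    panels. A serial-transfer simulator with per-lineage dynamics,
    mutation supply, bottleneck sampling and plate rendering generates
    synthetic experiments with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
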