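Package: braincomm
Title: Information-Theoretic Communication Regimes in Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint analysis of structural and functional brain connectomes
    through an information-theoretic lens. Estimates mutual-information
    functional connectomes from regional BOLD time series by uniform
    binning, computes fiber-length shortest paths on the structural
    connectome, and scores every source-target pair with the path
    processing score (PPS) and the path broadcasting strength (PBS).
    Pairs are classified into communication regimes (absent, relay,
    transducted, direct), nodal sender/receiver broadcasting strengths
    are derived per regime, and results are stratified by functional
    network. Includes a synthetic-data module (spatially embedded
    structural graphs, Gaussian time series with analytically known
    mutual information, Markov-chain relays) so every stage is testable
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
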