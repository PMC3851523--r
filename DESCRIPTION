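Package: apmsEnsemble
Title: Ensemble Sampling of Binary Realizations for Quantitative AP-MS
    Interaction Scoring
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Incorporates quantitative spectral-count information from
    affinity-purification mass-spectrometry (AP-MS) experiments into
    protein-protein interaction inference methods that operate on binary
    presence/absence data. Each spectral count is converted to an
    observation probability 1 - (1 - p)^n, an ensemble of Bernoulli binary
    realizations of the bait-prey matrix is drawn, each realization is
    scored with a binary co-occurrence scorer (Hart-style Poisson or
    hypergeometric null model, socio-affinity index, purification
    enrichment, or raw co-occurrence counts), and per-pair scores are
    averaged over the ensemble. Also provides a spectral-count-ranking
    baseline, top-K validation against multi-source gold standards, a
    reliability-parameter sweep, and a synthetic AP-MS generator with
    planted complexes and a sticky-contaminant background so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, MassSpectrometry, NetworkInference, Software
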