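Package: pedscan
Title: Variance-Component Linkage and Family-Based Rare-Variant Analysis of Blood Pressure Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing rare quantitative-trait variants in extended
    pedigrees. Implements multipoint identity-by-descent estimation with the
    Lander-Green inheritance-vector hidden Markov model, variance-component
    linkage scans with per-family LOD decomposition, family-based single-variant
    association via linear mixed models with kinship, burden/SKAT/SKAT-O
    rare-variant set tests under a polygenic covariance, a candidate-variant
    filtering and genotype risk-score conditional-linkage procedure with an
    empirical LOD-drop resampling null, and a gene-dropping simulator that
    emulates a family blood-pressure study design for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
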