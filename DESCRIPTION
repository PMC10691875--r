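Package: fluencygraph
Title: Qualitative Scoring, Sequence Embedding and Community Modelling of
    Phonemic Fluency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing performance on the phonemic ('S')
    verbal fluency test beyond the raw correct-word count. Implements
    single-word qualitative scoring (rule-break error taxonomy,
    perseverations, corpus-frequency-based low-frequency word detection,
    Troyer-style clustering and switching), whole-sequence analysis via
    deterministic feature-hashing embeddings and cosine-similarity
    participant graphs, community detection with a degree-corrected
    stochastic block model fitted by description-length minimization with
    edge covariates, Bayesian logistic regression (Polya-Gamma Gibbs
    sampling with ridge and horseshoe priors) for lesion-status
    prediction compared by pseudo-R2 and WAIC, and the accompanying
    group-statistics battery (ANCOVA with covariates, Bonferroni-corrected
    contrasts, categorical tests). A synthetic cohort generator emulates
    the group-level statistical structure of frontal/posterior lesion and
    control samples so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    mclust,
    emmeans,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
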