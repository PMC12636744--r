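Package: vaxbiome
Title: Gut Microbiome Correlates of Vaccine-Induced Immune Reactivity
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline linking baseline gut-metagenome composition to
    vaccine-induced cellular and humoral immune reactivity. Builds binary
    responder groups from immunoassay readouts (multiplex cytokine panels,
    whole-blood IFN-gamma release, ELISPOT median splits, antibody booster
    rules), models per-taxon differential relative abundance with log-link
    gamma regression and per-gene RPK abundance with negative-binomial
    regression, pools cohorts by Paule-Mandel random-effects meta-analysis
    with Benjamini-Yekutieli FDR control, benchmarks cross-cohort random
    forest prediction (repeated stratified CV, LODO and X-LODO), and scores
    samples ecologically (alpha/beta diversity, PERMANOVA, SIG1/Grey/SIG2
    categories). Ships a multi-cohort synthetic data generator with planted
    effects so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    MASS
Config/testthat/edition: 3
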