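Package: immprog
Title: Immune Microenvironment Progression Analysis for Post-Transplant Myeloma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bone-marrow immune microenvironment data
    collected before and after autologous stem cell transplant in multiple
    myeloma. Provides cell-level quality control and per-sample cell-type
    proportion statistics with a joint P/FDR significance rule, T-cell
    receptor clonal-expansion binning and chao1 repertoire diversity,
    survival machinery (Kaplan-Meier, log-rank, Efron-tie Cox regression,
    maximally selected survival cutpoints), an L1-penalized Cox model over
    cell-type proportions and all pairwise interaction terms fitted by cyclic
    coordinate descent, a leave-one-out ensemble with coefficient occurrence
    counting and highest-R2 model selection, cross-cohort cell-type
    harmonization and hazard scoring, and a seeded Dirichlet-multinomial
    cohort simulator with ground-truth access for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    survival,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
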