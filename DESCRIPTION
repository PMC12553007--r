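Package: mrtriad
Title: Triangulated Mendelian Randomisation of Proteins, Metabolites and
    Coronary Heart Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-layer summary-statistic Mendelian randomisation with
    generalised least squares (GLS) inverse-variance-weighted and MR-Egger
    estimators that account for residual linkage disequilibrium among
    instruments, instrument selection (cis windows, F-statistic and minor
    allele frequency filters, LD clumping), leverage and outlier pruning,
    and IVW-versus-Egger model selection.  Directionally concordant
    protein-metabolite-disease triangles are screened with principal
    component based Bonferroni thresholds and replicated across protein
    studies.  Prioritised proteins are followed up with plaque
    vulnerability association models, one-versus-rest Wilcoxon cell-type
    enrichment in single-cell expression data, hypergeometric
    over-representation analysis and druggability annotation.  A
    synthetic-data module generates every input with known ground truth
    so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
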