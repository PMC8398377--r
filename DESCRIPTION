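Package: radmetab
Title: Plasma Metabolomics Pipeline for Radiation Injury Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical workflow for untargeted plasma metabolomics studies of
    abdominal irradiation in nonhuman primates: plasma-volume normalization,
    detection-based missingness filtering, log transformation and minimum-value
    imputation; per-metabolite fold change with two-sided Welch tests and
    Benjamini-Hochberg adjustment; PCA and orthogonal partial least squares
    discriminant analysis (OPLS-DA) with VIP scores, stratified k-fold Q2,
    CV-ANOVA and permutation validation; hypergeometric subpathway enrichment;
    composite biomarker selection with time-varying-confounder (sham drift)
    filtering; and a design-faithful synthetic cohort generator with planted
    ground-truth effects for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
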