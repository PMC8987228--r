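Package: invpap
Title: Proteomic Biomarker Discovery for Inverted Urothelial Papilloma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a label-free proteomic
    biomarker-discovery workflow that distinguishes inverted urothelial
    papilloma (IUP) from papillary urothelial carcinoma (PUC) with inverted
    growth. Provides presence filtering, log transformation, median-centring
    and downshifted-normal imputation for iBAQ-style abundance matrices;
    permutation-based two-group t-tests and one-way ANOVA with SAM-style
    permutation false-discovery-rate control; partitioning of
    ANOVA-significant proteins into 'NU-like' and 'PUC-like' signature
    classes; support-vector-machine recursive feature elimination (RBF
    kernel) with cross-validated error curves and panel selection; a Human
    Protein Atlas immunoscore concordance screen; immunohistochemistry
    H-score quantification with Mann-Whitney comparison, AUROC,
    Youden-optimal cutoffs and exact binomial confidence intervals;
    univariate Cox and median-split Kaplan-Meier survival screening; and
    seeded synthetic-data generators emulating the study cohorts for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    survival
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
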