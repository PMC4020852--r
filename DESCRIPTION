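Package: receptorSig
Title: Receptor-Specific Gene-Signature Discovery from Ligand-Response
    Expression Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers gene signatures attributable to a single cell-surface
    receptor by boolean set-logic attribution of ligand-response genes across
    cell lines with known receptor expression patterns. Implements
    fold-change based differential-response calling of microarray probe sets,
    receptor-design identifiability checks, cross-line attribution and
    gene-level collapse, together with the downstream validation statistics
    used to qualify a candidate biomarker: housekeeping normalization,
    quartile stratification of patient cohorts with Kruskal-Wallis and Dunn's
    post-test, Spearman correlation with exact small-sample p-values, and
    two-group intervention analysis (tumor volume, percent decrease, unpaired
    t-test). A synthetic-data module with planted ground truth drives all
    analyses without external downloads; a GEO Series Matrix loader supports
    re-analysis of deposited expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, Microarray, DifferentialExpression, Software
RoxygenNote: 7.3.3
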