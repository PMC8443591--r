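Package: skinomics
Title: Multi-Block Integration of Skin Metabolome, Microbiome and PAH Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline linking chronic pollution exposure to skin
    biology in a two-city observational cohort design. Provides a PCA-based
    hair-PAH exposure score with median split, SAS-compatible Wilcoxon and
    chi-squared tests for ordinal and binary clinical signs, fold-change /
    Welch-t / Benjamini-Hochberg volcano screening of metabolite tables with
    pathway aggregation, random-forest city classification with permutation
    variable importance, rank-1 sparse canonical correlation analysis by
    penalized matrix decomposition with permutation-based sparsity tuning and
    significance, Pearson and PLS1 links between the metabolome and microbial
    Shannon diversity, a MAXVAR-A consensus space over multiple omics blocks
    realized as superblock regularized generalized CCA with Ward clustering,
    and v-test characterization of the resulting subject clusters. A
    synthetic multi-block cohort generator with planted ground truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
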