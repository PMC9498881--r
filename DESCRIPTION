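Package: snpmincut
Title: Clustering Genetic Variants by Shared Brain Association Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines high-level imaging-genetic associations by clustering
    candidate variants with similar brain association patterns. Builds
    SNP-by-ROI significance maps from covariate-adjusted linear regressions
    of imaging quantitative traits on additive genotype dosages, converts
    the row-normalized maps into multiple SNP-SNP similarity networks
    (Pearson, Spearman, Manhattan, Euclidean, cosine), clusters SNPs
    jointly across the networks with a multigraph min-max graph cut solved
    by projected gradient descent, selects the number of clusters by
    averaged silhouette analysis with a small-K preference, and exports
    per-cluster gene lists and mean brain association patterns. Includes a
    synthetic-cohort generator with planted SNP-cluster structure for
    end-to-end validation, and an exhaustive partition solver used as a
    correctness oracle.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
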