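Package: preservstat
Title: Statistical Comparison of Sample Preservation Treatments in Microbiome Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for paired-preservation microbiome studies in which
    replicate samples from several source materials are split between two treatments
    (for example heat-dried versus frozen). Implements material-stratified permutation
    tests for treatment effects on scalar success metrics (ratio-of-means statistic),
    a treatment-consistency test on log-transformed mean feature proportions,
    abundance-weighted Bray-Curtis dissimilarities with one-way PERMANOVA
    (pseudo-F, R-squared, standardized effect size) and two-dimensional metric
    multidimensional scaling by Kruskal-stress minimization, gene-centric functional
    profile arithmetic (contig, protein-coding gene, KEGG ortholog and KEGG level-C
    group proportions), per-sample diversity metrics, and a synthetic-data generator
    reproducing the material-by-treatment design structure for testing and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), vegan, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
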