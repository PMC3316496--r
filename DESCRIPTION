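Package: mirsignet
Title: Paired miRNA Differential Expression, Conditional Random-Forest
    Importance and Weighted Correlation Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering candidate driver microRNAs from paired
    tumour/normal expression profiles. Implements paired t-tests with
    Benjamini-Hochberg false discovery rate control and the signed
    fold-change convention, a random-forest tissue classifier with
    out-of-bag error, proximity-matrix multidimensional scaling and
    Strobl-style conditional permutation importance (mean decrease in
    accuracy), merging of the two rankings into a tissue-specific
    signature, significance-filtered weighted Spearman correlation
    networks with degree, betweenness, Zhang-Horvath weighted clustering,
    Schank-Wagner average weighted clustering and node-removal robustness
    ranking, and qPCR validation statistics (2^-ddCt relative
    quantification, Wilcoxon signed-rank tests against unity, power
    simulation). A synthetic paired-cohort generator with planted
    differential-expression effects and correlated feature modules makes
    the whole pipeline testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
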