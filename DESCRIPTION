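Package: tiestar
Title: Discovery of Multiple Markov Boundary Signatures with TIE* and HITON-PC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the full set of maximally predictive, non-redundant
    molecular signatures (Markov boundaries) of a phenotype from tabular
    omics data. Implements the TIE* multiple-boundary driver over the
    HITON-PC local causal discovery algorithm, conditional-independence
    testing (G2 for discrete data, Fisher-z for continuous data), baseline
    multiple-signature extractors (iterative removal, bootstrap resampling,
    KIAMB), discrete Bayesian network simulators with a known ground-truth
    boundary set, an exact small-network enumeration oracle, and signature
    predictivity evaluation by repeated-holdout AUC with Wilcoxon rank-sum
    comparisons.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    e1071,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
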