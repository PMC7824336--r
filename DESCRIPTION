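Package: entropymatch
Title: Entropy-Guided Selection of Exact String-Matching Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds domain models that rank classical exact string-matching
    algorithms (brute force, Morris-Pratt, Knuth-Morris-Pratt,
    Apostolico-Crochemore, Quick Search, Boyer-Moore and Horspool) by the
    number of pattern-versus-text character comparisons they perform,
    stratified by the Shannon entropy of the search pattern. Provides
    instrumented implementations of the seven matchers, pattern-entropy and
    frequency-distribution discretization utilities, finite-population
    sample-size calculation, campaign execution with quartile-share model
    building and prediction, model validation via the double-scaled
    Euclidean distance and Pearson correlation, and corpus input/output
    including synthetic DNA and natural-language corpus generation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
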