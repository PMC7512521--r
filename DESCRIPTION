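Package: logbounds
Title: Informational Indexes and the Log-Bounds Randomness Test for Finite Strings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes informational indexes of finite symbol strings
    (substring multiplicity, maximum repeat length, minimum hapax length,
    maximum complete length, empirical k-mer entropy) with an exact
    linear-time suffix-array backend, and applies the log-bounds randomness
    test, which compares the shortest-unique and longest-repeated substring
    lengths of string prefixes against the logarithmic reference values
    ceiling(log_m n) and ceiling(2 log_m n).  Includes exact
    arbitrary-precision generators for the decimal digits of pi, e and
    sqrt(2), Champernowne's constant, logistic-map discretizations, linear
    congruential generators and uniform i.i.d. strings, plus plain-text and
    FASTA readers and TSV/JSON report serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
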