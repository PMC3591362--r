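Package: specount
Title: Spectral-Count Differential Proteomics with Permutation Statistics
    and Shrunken-Centroid Classifiers
Version: 0.1.0
Authors@R:
    person("BALF", "Proteomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for label-free shotgun-proteomics studies quantified by
    spectral counting. Implements presence filtering, the spectral-index
    differential-abundance statistic with an empirical permutation null,
    correspondence analysis of count tables, hierarchical and K-medians
    clustering, nearest-shrunken-centroid (PAM) classifier training with
    cross-validation, limited-signature selection, a combined normalized-sum
    classifier score with ROC evaluation, over-representation analysis with
    permutation p-values, and a ground-truth synthetic spectral-count
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
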