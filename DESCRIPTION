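Package: exactLogrank
Title: Exact Permutational Log-Rank Tests for Genome-Wide Survival Screens
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the two-sample log-rank test under the exact
    permutational null distribution, in which all assignments of the
    group-1 labels to the observed (time, censoring) sequence are equally
    likely.  The p-value is obtained by a fully polynomial-time
    approximation scheme over step-function representations of the tail
    probabilities, with a guaranteed conservative (1+epsilon) bound, or
    exactly by enumeration and an undiscretized dynamic program at small
    sample sizes.  Also provides the exact conditional (hypergeometric)
    test, Monte-Carlo estimation with Clopper-Pearson intervals, the
    asymptotic normal and chi-squared approximations under both variance
    conventions, a somatic-mutation survival screening pipeline with
    metagene collapsing, Monte-Carlo prescreening and null-distribution
    caching, and synthetic-data generators for null calibration
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), survival, withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
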