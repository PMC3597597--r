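Package: cidgsaa
Title: Gene Set Association Analysis with the Coefficient of Intrinsic
    Dependence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies statistical dependence between two gene sets
    across expression profiles using the coefficient of intrinsic
    dependence (CID), a [0,1]-valued measure built from discrepancies
    between the marginal and conditional empirical distribution
    functions of the target gene set, conditioning on subgroups of
    samples obtained by clustering the predictor gene set.  Includes
    regularized canonical-variate reduction for high-dimensional gene
    sets, permutation tests and a median/MAD outlier screen for
    all-pairs analysis, rival association measures (canonical
    correlation, Kullback-Leibler and Hellinger distances, projection
    pursuit regression) and simulation models for benchmarking type-I
    error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    class,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
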