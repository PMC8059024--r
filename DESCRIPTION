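Package: gsdist
Title: Gene-Set Distance Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-contained, model-free association testing between a gene-set
    expression matrix and a quantitative, categorical, or censored event-time
    variable via the bias-corrected distance correlation t-test. Includes fast
    permutation verification operating on U-centered distance matrices,
    screening of gene-set collections with false discovery rate adjustment,
    a backward-elimination procedure to identify the genes that empirically
    drive a significant association, and a simulation harness for estimating
    empirical level and power under simple and complex (differential
    correlation) association structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
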