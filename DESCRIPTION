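Package: mircleave
Title: Plant miRNA Target Prediction, Degradome Validation, and Expression
    Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for small-RNA studies in plants lacking a
    sequenced genome: weighted-complementarity miRNA target prediction with
    G:U wobble and 5'-core penalty doubling, degradome (PARE) cleavage-site
    validation with t-plots and category I/II/III classification,
    two-channel microarray differential expression with LOWESS dye-bias
    normalization and paired t-tests, and 2^-ddCt qRT-PCR relative
    quantification. Seeded synthetic-data generators with machine-readable
    truth tables make every stage testable at desk scale without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
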