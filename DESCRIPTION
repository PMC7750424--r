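Package: aacap
Title: Amino-Acid Composition, Media Capacity, and Antibody Production Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Profiles antibody signal peptides and full-length chains by
    essential/non-essential amino-acid content, converts culture-media
    formulations into per-amino-acid molecule supply to identify limiting
    amino acids and the theoretical maximum antibody yield, and fits a
    three-class one-vs-rest L2-regularised logistic model predicting
    recombinant production-rate categories from amino-acid counts, with a
    cross-validated regularisation path, replicate evaluation protocol, and a
    seeded synthetic variant-production generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
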