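Package: barcodegap
Title: DNA Barcode-Gap Species Delimitation and Mini-Barcode Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delimiting closely related species from aligned COI
    DNA barcodes: Kimura 2-parameter distances with pairwise deletion,
    BioNJ tree construction with column-resampling bootstrap, within- and
    between-group divergence statistics and barcode-gap tests,
    single-linkage cluster delimitation at a distance threshold, discovery
    of fixed diagnostic nucleotide positions between species, design of
    short "ID tag" mini-barcode windows for degraded museum DNA with
    degenerate-primer virtual PCR and fragment-based species calling, a
    genitalic ratio discriminant for two-group morphometric separation,
    and a transition-biased sequence simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
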