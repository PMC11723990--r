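Package: radicans
Title: CAPS Genotyping, Ploidy Calling, and Morphometric Discrimination
    for the Vandenboschia radicans Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated identification pipeline for allopolyploid
    filmy-fern hybrids of the Vandenboschia radicans complex. Designs
    diagnostic CAPS (cleaved amplified polymorphic sequence) markers by
    in-silico restriction digestion of class-labelled nuclear GapCp
    alleles, predicts and calls gel band patterns for pure and hybrid
    genotypes, estimates 2C genome size and ploidy from flow-cytometry
    G1-peak ratios against an internal standard, assembles genomic
    formulas (alpha/beta/gamma genome symbols with asterisk slots for
    unresolved dosage) from chloroplast rbcL haplotypes and cloned
    nuclear alleles, maps formulas to taxa, and discriminates genotype
    groups morphometrically via univariate test-selection logic and
    discriminant analysis of principal components (DAPC). A synthetic
    cohort generator with known truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    MASS,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
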