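Package: recmapper
Title: Autozygosity Mapping and Private-Variant Discovery for Recessive
    Disease in Consanguineous Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Positional cloning toolkit for monogenic recessive disorders
    in inbred pedigrees, built around the trio homozygosity-mapping strategy
    used in livestock disease genetics. Provides pedigree kinship and
    inbreeding coefficients, obligate-carrier inference, gene-dropping
    simulation of autozygosity, runs-of-homozygosity detection with
    parental-exclusion mapping, private small-variant filtering against a
    control cohort, discordant read-pair deletion calling with diploid
    genotyping, and loss-of-function consequence classification including
    start-codon loss and downstream start-codon rescue. A seeded
    synthetic-cohort generator emulates a dense SNP array, unrelated control
    genomes and a paired-end fragment library over a planted recessive
    deletion, so the whole pipeline can be exercised end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
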