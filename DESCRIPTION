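Package: sexscan
Title: Coverage-Based Discovery of Sex-Specific Genomic Regions and
    PCR Sexing Assay Design
Version: 0.1.0
Authors@R:
    person("sexscan", "developers", email = "sexscan@example.org",
           role = c("aut", "cre"))
Description: Discovers sex-specific (e.g. W-linked) genomic regions from
    per-base read-depth tables of phenotypically sexed individuals using a
    per-position Welch's t-test combined with presence/absence rules, merges
    significant positions into regions, and verifies hemizygosity via the
    region-to-genome depth ratio. Locates each region's paralog in the
    reference, aligns the pair with an affine-gap (Gotoh) global aligner,
    inventories deletion-type structural variants, annotates open reading
    frames, and designs a single primer pair in conserved flanking sequence
    whose two co-amplified products resolve heterogametic (ZW) from
    homogametic (ZZ) individuals on a gel. Includes a seeded synthetic-data
    generator that plants a hemizygous region with known deletions for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
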