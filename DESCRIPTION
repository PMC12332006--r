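Package: misplice
Title: Minor Intron Mis-Splicing Quantification from RNA-Seq Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Catalogs introns from genome annotation and classifies them as
    minor (U12-type) or major (U2-type) by database lookup or splice-site
    position-weight-matrix scoring; counts exon-intron boundary reads,
    canonical and aberrant exon-exon junction reads and intron-body coverage
    from spliced alignments; computes per-intron mis-splicing indices for
    retention (MSI_ret) and alternative splicing (MSI_AS) and the
    IRFinder-style IR ratio; calls differential intron retention between two
    replicated conditions with Welch's t-test, the Audic-Claverie exact count
    test, Benjamini-Hochberg FDR control and an explicit four-rule retention
    filter; and aggregates calls into gene-level event categories and
    minor-versus-major enrichment summaries. Ships a synthetic-data module
    that generates a toy genome, annotation with planted minor introns and
    replicated read sets with known retention and alternative-splicing
    fractions, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
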