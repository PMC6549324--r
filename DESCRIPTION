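Package: genefeatr
Title: Gene Feature Tables and Descriptive Statistics from Curated Genome Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives per-transcript gene features (exons, coding-exon
    portions, introns, UTR/CDS splits) from protein-coding gene models read
    from GFF3 or GTF, applies a curation policy over RefSeq statuses to
    define an analysis set, collapses features shared across transcript
    isoforms into non-redundant sets, exports a three-table spreadsheet-style
    dialect (genes, transcripts and one row per exon with its companion
    intron), and computes the full battery of descriptive statistics for
    gene, mRNA, exon, coding-exon and intron numbers and lengths, including
    release-over-release percent changes. A seeded synthetic-annotation
    generator with exact ground truth makes the whole pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
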