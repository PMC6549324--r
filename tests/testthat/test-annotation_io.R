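gff3_fixture <- function(path, reversed = FALSE) {
  exon_lines <- c(
    "NC_000001.11\ttest\texon\t100\t200\t.\t+\t.\tParent=rna-NM_000010.1",
    "NC_000001.11\ttest\texon\t301\t400\t.\t+\t.\tParent=rna-NM_000010.1",
    "NC_000001.11\ttest\texon\t501\t600\t.\t+\t.\tParent=rna-NM_000010.1"
  )
  if (reversed) exon_lines <- rev(exon_lines)
  writeLines(c(
    "##gff-version 3",
    paste0("NC_000001.11\ttest\tgene\t100\t600\t.\t+\t.\t",
           "ID=gene-10;gene_id=10;Name=G10;gene_biotype=protein_coding;",
           "gene_refseq_status=REVIEWED;chromosome=1"),
    paste0("NC_000001.11\ttest\tmRNA\t100\t600\t.\t+\t.\t",
           "ID=rna-NM_000010.1;Parent=gene-10;transcript_id=NM_000010.1;",
           "transcript_refseq_status=VALIDATED;protein_id=NP_000010.1"),
    exon_lines,
    "NC_000001.11\ttest\tCDS\t150\t200\t.\t+\t0\tParent=rna-NM_000010.1",
    "NC_000001.11\ttest\tCDS\t301\t380\t.\t+\t0\tParent=rna-NM_000010.1"
  ), path)
  path
}

test_that("a 3-exon GFF3 fixture imports with conserved lengths", {
  p <- gff3_fixture(withr::local_tempfile(fileext = ".gff3"))
  set <- read_gff3(p)
  expect_equal(nrow(set$genes), 1L)
  expect_equal(set$genes$chromosome, "1") # text, from the attribute
  ts <- transcript_summaries(set)
  expect_equal(ts$n_exons, 3L)
  expect_equal(ts$transcript_len, 301L) # 101 + 100 + 100
  expect_equal(set$transcripts$cds_start, 150L)
  expect_equal(set$transcripts$cds_end, 380L)
  expect_equal(ts$cds_len, 131L) # 51 + 80
  # defaults for unstated currency/liveness
  expect_true(set$genes$in_current_annotation)
  expect_true(set$genes$live_status)
})

test_that("GFF3 import is independent of feature line order", {
  p1 <- gff3_fixture(withr::local_tempfile(fileext = ".gff3"))
  p2 <- gff3_fixture(withr::local_tempfile(fileext = ".gff3"), reversed = TRUE)
  expect_sets_equal(read_gff3(p1), read_gff3(p2))
})

test_that("orphan Parent references fail fast in strict mode only", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste0("NC_000001.11\ttest\tgene\t100\t600\t.\t+\t.\t",
           "ID=gene-10;gene_biotype=protein_coding;gene_refseq_status=REVIEWED"),
    paste0("NC_000001.11\ttest\tmRNA\t100\t600\t.\t+\t.\t",
           "ID=rna-A;Parent=gene-MISSING;transcript_id=NM_000010.1"),
    "NC_000001.11\ttest\texon\t100\t600\t.\t+\t.\tParent=rna-A"
  ), p)
  expect_error(read_gff3(p, strict = TRUE), "orphan Parent")
  # lenient mode warns once per skipped record (mRNA, then its exon)
  ws <- capture_warnings(set <- read_gff3(p, strict = FALSE))
  expect_true(all(grepl("orphan Parent", ws)))
  expect_equal(nrow(set$transcripts), 0L)
})

test_that("GTF stop_codon features are merged into the CDS span", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("NC_000001.11\ttest\tgene\t50\t250\t.\t+\t.\t",
           'gene_id "1"; gene_name "G1"; gene_biotype "protein_coding"; ',
           'gene_refseq_status "REVIEWED"; chromosome "1";'),
    paste0("NC_000001.11\ttest\ttranscript\t50\t250\t.\t+\t.\t",
           'gene_id "1"; transcript_id "NM_000001.1"; ',
           'transcript_refseq_status "VALIDATED";'),
    paste0("NC_000001.11\ttest\texon\t50\t250\t.\t+\t.\t",
           'gene_id "1"; transcript_id "NM_000001.1";'),
    paste0("NC_000001.11\ttest\tCDS\t100\t196\t.\t+\t0\t",
           'gene_id "1"; transcript_id "NM_000001.1";'),
    paste0("NC_000001.11\ttest\tstop_codon\t197\t199\t.\t+\t0\t",
           'gene_id "1"; transcript_id "NM_000001.1";')
  ), p)
  set <- read_gtf(p)
  expect_equal(set$transcripts$cds_start, 100L)
  expect_equal(set$transcripts$cds_end, 199L)
  expect_equal(transcript_summaries(set)$cds_len, 100L)
})

test_that("minus-strand stop_codon merging is coordinate-correct", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("NC_000001.11\ttest\tgene\t150\t350\t.\t-\t.\t",
           'gene_id "2"; gene_name "G2"; gene_biotype "protein_coding"; ',
           'gene_refseq_status "REVIEWED"; chromosome "1";'),
    paste0("NC_000001.11\ttest\ttranscript\t150\t350\t.\t-\t.\t",
           'gene_id "2"; transcript_id "NM_000002.1"; ',
           'transcript_refseq_status "REVIEWED";'),
    paste0("NC_000001.11\ttest\texon\t150\t350\t.\t-\t.\t",
           'gene_id "2"; transcript_id "NM_000002.1";'),
    paste0("NC_000001.11\ttest\tCDS\t203\t299\t.\t-\t0\t",
           'gene_id "2"; transcript_id "NM_000002.1";'),
    paste0("NC_000001.11\ttest\tstop_codon\t200\t202\t.\t-\t0\t",
           'gene_id "2"; transcript_id "NM_000002.1";')
  ), p)
  set <- read_gtf(p)
  expect_equal(set$transcripts$cds_start, 200L)
  expect_equal(set$transcripts$cds_end, 299L)
})

test_that("the same models written as GFF3 and GTF import identically", {
  gen <- generate_annotation(generator_params(n_genes = 12, seed = 31))
  d <- withr::local_tempdir()
  pg <- file.path(d, "m.gff3"); pt <- file.path(d, "m.gtf")
  write_gff3(gen$set, pg)
  write_gtf(gen$set, pt)
  from_gff <- read_gff3(pg)
  from_gtf <- read_gtf(pt)
  expect_sets_equal(from_gff, from_gtf)
  expect_sets_equal(from_gff, gen$set)
})

test_that("the edge fixtures survive a GFF3 round trip", {
  d <- withr::local_tempdir()
  p <- file.path(d, "edge.gff3")
  write_gff3(make_edge_fixtures(), p)
  expect_sets_equal(read_gff3(p), make_edge_fixtures())
})

test_that("three-table export writes the documented columns and row counts", {
  d <- withr::local_tempdir()
  set <- tiny_set()
  paths <- write_three_tables(set, d)
  genes_tab <- read.delim(paths[["genes"]], colClasses = "character")
  expect_equal(nrow(genes_tab), 2L)
  expect_equal(genes_tab$Chromosome, c("1", "X"))
  gt_tab <- read.delim(paths[["gene_table"]], colClasses = "character",
                       check.names = FALSE)
  expect_equal(nrow(gt_tab), 7L) # sum of n_exons over transcripts
  # seeded synthetic set: row count equals total exon count
  gen <- generate_annotation(generator_params(n_genes = 20, seed = 8))
  paths2 <- write_three_tables(gen$set, d, prefix = "syn_")
  gt2 <- read.delim(paths2[["gene_table"]], colClasses = "character")
  expect_equal(nrow(gt2), nrow(gen$set$exons))
})

test_that("a mono-exonic gene yields one row with Last_Exon and empty intron cells", {
  d <- withr::local_tempdir()
  fix <- make_edge_fixtures()
  keep <- fix$genes$symbol == "MONO1"
  mono <- annotation_set(fix$genes[keep, ],
                         fix$transcripts[fix$transcripts$gene_id %in%
                                           fix$genes$gene_id[keep], ],
                         fix$exons[fix$exons$gene_id %in%
                                     fix$genes$gene_id[keep], ])
  p <- file.path(d, "mono.tsv")
  write_gene_table(mono, p)
  tab <- read.delim(p, colClasses = "character", check.names = FALSE)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$Last_Exon, "Yes")
  expect_equal(tab$Intron_Start, "")
  expect_equal(tab$Intron_Length_bp, "")
})

test_that("an empty set writes header-only tables", {
  d <- withr::local_tempdir()
  set <- tiny_set()
  empty <- annotation_set(set$genes[0, ], set$transcripts[0, ], set$exons[0, ])
  paths <- write_three_tables(empty, d)
  for (p in paths) {
    expect_equal(length(readLines(p)), 1L)
  }
})

test_that("the three-table dialect round-trips byte-identically", {
  d <- withr::local_tempdir()
  gen <- generate_annotation(generator_params(n_genes = 15, seed = 23))
  p1 <- file.path(d, "gt1.tsv"); p2 <- file.path(d, "gt2.tsv")
  write_gene_table(gen$set, p1)
  set2 <- read_gene_table(p1)
  write_gene_table(set2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_sets_equal(set2, gen$set)
})

test_that("non-redundancy labels are preserved verbatim through the dialect", {
  d <- withr::local_tempdir()
  p <- file.path(d, "gt.tsv")
  write_gene_table(tiny_set(), p)
  tab <- read.delim(p, colClasses = "character", check.names = FALSE,
                    encoding = "UTF-8")
  expect_true("Yes—Merged" %in% tab$Non_Redundant_Exon)
  expect_true("Yes—Unique" %in% tab$Non_Redundant_Exon)
  expect_true(any(tab$Non_Redundant_Exon == ""))
})

test_that("inconsistent stated lengths raise an integrity error naming the row", {
  d <- withr::local_tempdir()
  p <- file.path(d, "gt.tsv")
  write_gene_table(tiny_set(), p)
  lines <- readLines(p, encoding = "UTF-8")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  row <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  row[header == "Exon_Length_bp"] <- "99"
  lines[2] <- paste(row, collapse = "\t")
  writeLines(lines, p, useBytes = TRUE)
  expect_error(read_gene_table(p), "integrity error.*row 1")
})

test_that("the shipped data dictionary covers every exported column", {
  dict <- read.delim(
    system.file("extdata", "data_dictionary.tsv", package = "genefeatr"),
    colClasses = "character"
  )
  expect_setequal(dict$column[dict$table == "Genes"],
                  genefeatr:::GENES_TSV_COLS)
  expect_setequal(dict$column[dict$table == "Transcripts"],
                  genefeatr:::TRANSCRIPTS_TSV_COLS)
  expect_setequal(dict$column[dict$table == "Gene_Table"],
                  genefeatr:::GENE_TABLE_TSV_COLS)
  expect_true(all(nzchar(dict$description)))
})
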