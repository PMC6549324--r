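test_that("introns fill the gaps between transcription-ordered exons", {
  t <- transcript_record("NM_1", "NC_1", "+",
                         c(101, 301, 501), c(200, 400, 600))
  ins <- derive_introns(t)
  expect_equal(ins$start, c(201L, 401L))
  expect_equal(ins$end, c(300L, 500L))
  expect_equal(ins$length, c(100L, 100L))
  expect_equal(ins$intron_serial, 1:2)
  # mono-exonic: no introns
  expect_equal(nrow(derive_introns(transcript_record("NM_2", "NC_1", "+",
                                                     100, 500))), 0L)
  # minus strand: transcription order descending; intron 1 lies genomically
  # between the two exons
  tm <- transcript_record("NM_3", "NC_1", "-", c(501, 301), c(600, 400))
  insm <- derive_introns(tm)
  expect_equal(insm$start, 401L)
  expect_equal(insm$end, 500L)
})

test_that("every transcript yields exactly n_exons - 1 introns", {
  for (seed in 1:30) {
    t <- random_transcript(seed, coding = FALSE)
    expect_identical(nrow(derive_introns(t)), length(t$exon_starts) - 1L)
  }
})

test_that("coding portions are exon/CDS intersections summing to the CDS length", {
  t <- transcript_record("NM_1", "NC_1", "+", 1, 300, 101, 250)
  ce <- derive_coding_exons(t)
  expect_equal(ce$start, 101L)
  expect_equal(ce$end, 250L)
  expect_equal(ce$length, 150L)
  # overlap of a single base: 1-bp coding exon
  t <- transcript_record("NM_2", "NC_1", "+", c(100, 300), c(200, 500),
                         200, 400)
  ce <- derive_coding_exons(t)
  expect_equal(ce$length, c(1L, 101L))
  expect_equal(ce$coding_serial, 1:2)
  # exon entirely 5' of the CDS has no coding portion but remains an exon
  t <- transcript_record("NM_3", "NC_1", "+", c(100, 300, 600),
                         c(200, 500, 700), 350, 650)
  ce <- derive_coding_exons(t)
  expect_equal(ce$exon_serial, 2:3)
  expect_equal(sum(ce$length), interval_length(350, 650) - 99L) # minus intron
  expect_error(derive_coding_exons(transcript_record("NM_4", "NC_1", "+",
                                                     1, 100)),
               "no CDS")
})

test_that("coding lengths always sum to the mRNA CDS length", {
  for (seed in 1:40) {
    t <- random_transcript(seed, coding = TRUE)
    expected <- attr(t, "mrna_cds")
    expect_identical(sum(derive_coding_exons(t)$length),
                     as.integer(expected[["cds"]]))
  }
})

test_that("UTR/CDS split partitions the transcript, strand-invariantly", {
  # + strand: 1000-bp mRNA, CDS starts 150 bp in, 600 bp long
  t <- transcript_record("NM_1", "NC_1", "+", c(1, 501), c(400, 1100))
  # mRNA pos 151 -> genomic 151; mRNA pos 750 -> genomic 501 + (750-400) - 1
  t$cds_start <- 151L; t$cds_end <- 850L
  sp <- split_utrs(t)
  expect_equal(sp, list(utr5_len = 150L, cds_len = 600L, utr3_len = 250L,
                        transcript_len = 1000L))
  # mirrored to the minus strand the split is unchanged
  tm <- mirror_transcript(t)
  expect_equal(split_utrs(tm)[1:3], sp[1:3])
  # CDS starting at mRNA base 1
  t2 <- transcript_record("NM_2", "NC_1", "+", 100, 599, 100, 399)
  expect_equal(split_utrs(t2)$utr5_len, 0L)
})

test_that("UTR/CDS split recovers the generating mRNA partition", {
  for (seed in 1:40) {
    t <- random_transcript(seed, coding = TRUE)
    want <- attr(t, "mrna_cds")
    got <- split_utrs(t)
    expect_identical(c(got$utr5_len, got$cds_len, got$utr3_len),
                     as.integer(want))
    tm <- mirror_transcript(t)
    gotm <- split_utrs(tm)
    expect_identical(gotm[1:3], got[1:3])
  }
})

test_that("exactly one exon is flagged last, by transcription order", {
  t <- transcript_record("NM_1", "NC_1", "+", c(1, 201, 401), c(100, 300, 500))
  expect_equal(flag_last_exons(t)$last_exon, c(FALSE, FALSE, TRUE))
  # minus strand: the last exon in transcription order is genomically left-most
  tm <- transcript_record("NM_2", "NC_1", "-", c(401, 201, 1), c(500, 300, 100))
  fl <- flag_last_exons(tm)
  expect_equal(fl$last_exon, c(FALSE, FALSE, TRUE))
  expect_equal(tm$exon_starts[fl$last_exon], 1L)
  expect_equal(flag_last_exons(transcript_record("NM_3", "NC_1", "+",
                                                 1, 100))$last_exon, TRUE)
})

test_that("last coding exon can precede the last exon", {
  # 3' UTR occupies the whole final exon
  t <- transcript_record("NM_1", "NC_1", "+", c(1, 201, 401),
                         c(100, 300, 500), 50, 250)
  fl <- flag_last_exons(t)
  expect_equal(fl$last_exon, c(FALSE, FALSE, TRUE))
  expect_equal(fl$last_coding_exon, c(FALSE, TRUE, FALSE))
})

test_that("non-redundancy labels one representative per identical-coordinate group", {
  gt <- build_gene_table(tiny_set())
  # ALPHA exon (1000,1099) is shared by both isoforms: one Merged, one blank
  shared <- gt[gt$exon_start == 1000 & gt$exon_end == 1099, ]
  expect_equal(sort(shared$nr_exon), c("", "Yes—Merged"))
  # the representative is the first under (gene, accession, serial) order
  expect_equal(shared$nr_exon[shared$transcript_accession == "NM_000001.1"],
               "Yes—Merged")
  # exon present in exactly one isoform
  unique_row <- gt[gt$exon_start == 1200, ]
  expect_equal(unique_row$nr_exon, "Yes—Unique")
})

test_that("non-redundancy labels match a brute-force group-by", {
  gen <- generate_annotation(generator_params(n_genes = 15, seed = 42))
  gt <- build_gene_table(apply_curation(gen$set)$set)
  for (fc in c("exon", "coding", "intron")) {
    scol <- paste0(fc, "_start"); ecol <- paste0(fc, "_end")
    ncol <- c(exon = "nr_exon", coding = "nr_coding", intron = "nr_intron")[[fc]]
    has <- !is.na(gt[[scol]])
    key <- paste(gt$chrom_accession, gt$strand, gt[[scol]], gt[[ecol]])[has]
    sizes <- table(key)
    labels <- gt[[ncol]][has]
    # exactly one non-blank label per group
    nonblank_per_group <- tapply(labels != "", key, sum)
    expect_true(all(nonblank_per_group == 1L))
    # Merged iff the group recurs
    lab_per_group <- tapply(labels, key, function(x) x[x != ""][1])
    expect_equal(unname(lab_per_group[names(sizes)] == "Yes—Merged"),
                 unname(sizes > 1))
  }
})

test_that("label partition is invariant to input row order", {
  gt <- build_gene_table(tiny_set())
  shuffled <- gt[sample(nrow(gt)), ]
  for (fc in c("exon", "coding", "intron")) {
    relabeled <- mark_non_redundant(shuffled, fc)
    ncol <- c(exon = "nr_exon", coding = "nr_coding", intron = "nr_intron")[[fc]]
    key <- paste(relabeled$transcript_accession, relabeled$exon_serial)
    orig_key <- paste(gt$transcript_accession, gt$exon_serial)
    expect_equal(relabeled[[ncol]][order(key)], gt[[ncol]][order(orig_key)])
  }
})

test_that("short introns are flagged below, not at, the threshold", {
  gt <- build_gene_table(make_edge_fixtures())
  flagged <- flag_short_introns(gt, threshold = 30L)
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$symbol, "SINT26")
  expect_equal(flagged$intron_serial, 4L)
  expect_equal(flagged$length, 26L)
  expect_equal(flagged$category, "non_canonical_excision_candidate")
  # the 30-bp intron sits exactly at the boundary and is not flagged
  expect_false("SINT30" %in% flagged$symbol)
  # threshold 0 flags nothing
  expect_equal(nrow(flag_short_introns(gt, threshold = 0L)), 0L)
  # 1-3 bp introns are classed as likely artifacts
  t <- transcript_record("NM_9", "NC_000001.11", "+", c(1, 104), c(100, 200))
  g <- data.frame(gene_id = "9", symbol = "ART1", chromosome = "1",
                  chrom_accession = "NC_000001.11", strand = "+",
                  gene_start = 1L, gene_end = 200L,
                  gene_type = "protein-coding",
                  gene_refseq_status = "REVIEWED",
                  in_current_annotation = TRUE, live_status = TRUE)
  tx <- data.frame(gene_id = "9", accession = "NM_9",
                   transcript_refseq_status = "REVIEWED",
                   protein_accession = NA_character_,
                   cds_start = NA_integer_, cds_end = NA_integer_)
  ex <- data.frame(gene_id = "9", accession = "NM_9", exon_serial = 1:2,
                   start = c(1L, 104L), end = c(100L, 200L))
  gt2 <- build_gene_table(annotation_set(g, tx, ex))
  fl <- flag_short_introns(gt2)
  expect_equal(fl$length, 3L)
  expect_equal(fl$category, "likely_artifact")
})

test_that("derived statistics are invariant under strand mirroring", {
  gen <- generate_annotation(generator_params(n_genes = 20, seed = 11))
  cur <- apply_curation(gen$set)$set
  mirrored <- mirror_set(cur, L = 400000000L)
  expect_reports_equal(build_report(mirrored), build_report(cur))
})
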