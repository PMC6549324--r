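test_that("summaries follow spreadsheet conventions", {
  s <- summarize_values(c(100, 200, 300))
  expect_equal(s$median, 200)
  expect_equal(s$mean, 200)
  expect_equal(s$sd, 100) # sample SD, n-1 denominator
  expect_equal(s$total, 600)
  # n = 1: SD undefined, reported empty (NA), not 0
  s1 <- summarize_values(7)
  expect_equal(s1$median, 7)
  expect_true(is.na(s1$sd))
  # even n: midpoint median
  expect_equal(summarize_values(c(1, 2, 3, 4))$median, 2.5)
  # empty input is a marker, not zeros
  s0 <- summarize_values(numeric(0))
  expect_equal(s0$n, 0L)
  expect_true(is.na(s0$total))
})

test_that("summaries match a brute-force two-pass reference", {
  set.seed(99)
  v <- rlnorm(1000, 5, 1.2)
  s <- summarize_values(v)
  # independent two-pass computation
  n <- 0; tot <- 0
  for (x in v) { n <- n + 1; tot <- tot + x }
  m <- tot / n
  ssq <- 0
  for (x in v) ssq <- ssq + (x - m)^2
  expect_equal(s$n, n)
  expect_equal(s$mean, m, tolerance = 1e-9)
  expect_equal(s$sd, sqrt(ssq / (n - 1)), tolerance = 1e-9)
  expect_equal(s$total, tot, tolerance = 1e-9)
  sv <- sort(v)
  expect_equal(s$median, (sv[500] + sv[501]) / 2, tolerance = 1e-9)
  expect_equal(s$min, sv[1])
  expect_equal(s$max, sv[1000])
})

test_that("extreme labels report all ties, sorted", {
  s <- summarize_values(c(26, 30, 30, 500),
                        labels = c("XBP1, I4", "RBP5, I2", "MST1L, I9",
                                   "BIG1, I1"))
  expect_equal(s$min_label, "XBP1, I4")
  expect_equal(s$max_label, "BIG1, I1")
  s2 <- summarize_values(c(30, 30), labels = c("RBP5, I2", "MST1L, I9"))
  expect_equal(s2$min_label, "MST1L, I9; RBP5, I2")
})

test_that("means from totals use half-away-from-zero rounding", {
  expect_equal(mean_from_totals(10, 4, 0), 3) # 2.5 rounds up
  expect_equal(mean_from_totals(-10, 4, 0), -3) # away from zero
  expect_equal(round_half_away(0.15, 1), 0.2)
  expect_equal(mean_from_totals(7, 2, 1), 3.5)
  expect_error(mean_from_totals(10, 0), "n <= 0")
})

test_that("percent changes reproduce the release-comparison convention", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(100, 150), 50)
  expect_equal(percent_change(200, 100), -50)
  expect_equal(percent_change(3, 4, 2), 33.33)
  expect_error(percent_change(0, 10), "old <= 0")
})

test_that("per-chromosome counts report extremes with ties", {
  set <- tiny_set()
  pc <- per_chromosome_counts(set)
  expect_equal(pc$counts, c("1" = 1L, "X" = 1L))
  expect_equal(sort(pc$min_chromosomes), c("1", "X"))
  gen <- generate_annotation(generator_params(n_genes = 50, seed = 13))
  cur <- apply_curation(gen$set)$set
  pc <- per_chromosome_counts(cur)
  expect_equal(sum(pc$counts), nrow(cur$genes))
  expect_equal(unname(pc$counts),
               as.integer(table(cur$genes$chromosome)[names(pc$counts)]))
  empty <- annotation_set(set$genes[0, ], set$transcripts[0, ], set$exons[0, ])
  expect_equal(length(per_chromosome_counts(empty)$counts), 0L)
})

test_that("not-last stats exclude exactly the last-exon records", {
  gt <- build_gene_table(tiny_set())
  # ALPHA T1 exons 100/100/100, T2 100/100; BETA 100/200:
  # not-last exon lengths are {100,100} (T1), {100} (T2), {100} (BETA)
  s <- not_last_exon_stats(gt, "exon")
  expect_equal(s$n, 4L)
  expect_equal(s$mean, 100)
  # hand example: two 2-exon transcripts with exon lengths [100,900], [50,900]
  g <- data.frame(gene_id = c("1", "2"), symbol = c("A", "B"),
                  chromosome = "1", chrom_accession = "NC_1", strand = "+",
                  gene_start = c(1L, 10000L), gene_end = c(2000L, 12000L),
                  gene_type = "protein-coding", gene_refseq_status = "REVIEWED",
                  in_current_annotation = TRUE, live_status = TRUE)
  tx <- data.frame(gene_id = c("1", "2"),
                   accession = c("NM_000011.1", "NM_000012.1"),
                   transcript_refseq_status = "REVIEWED",
                   protein_accession = NA_character_,
                   cds_start = NA_integer_, cds_end = NA_integer_)
  ex <- data.frame(
    gene_id = c("1", "1", "2", "2"),
    accession = rep(c("NM_000011.1", "NM_000012.1"), each = 2),
    exon_serial = c(1L, 2L, 1L, 2L),
    start = c(1L, 1001L, 10000L, 11000L),
    end = c(100L, 1900L, 10049L, 11899L)
  )
  s2 <- not_last_exon_stats(build_gene_table(annotation_set(g, tx, ex)), "exon")
  expect_equal(s2$n, 2L)
  expect_equal(s2$mean, 75)
  # an all-mono-exonic set has only last exons: empty marker
  ex1 <- ex[c(1, 3), ]; ex1$end <- c(2000L, 12000L)
  s3 <- not_last_exon_stats(build_gene_table(annotation_set(g, tx, ex1)), "exon")
  expect_equal(s3$n, 0L)
})

test_that("per-transcript count stats exclude mono-exonic records from the intron minimum", {
  gen <- generate_annotation(generator_params(n_genes = 10, seed = 2))
  cur <- apply_curation(gen$set)$set
  tsum <- transcript_summaries(cur)
  # transcripts with 1, 3 and 5 exons
  sub <- cur
  s <- per_transcript_count_stats(cur, "exon", tsum)
  expect_equal(s$total, sum(tsum$n_exons))
  si <- per_transcript_count_stats(cur, "intron", tsum)
  expect_equal(si$total, sum(tsum$n_exons - 1L))
  if (any(tsum$n_exons > 1L)) {
    expect_equal(si$min, min(tsum$n_introns[tsum$n_introns > 0]))
  }
})

test_that("hand-built two-gene fixture reproduces every report cell", {
  rep <- build_report(tiny_set())
  expect_equal(rep$genes$n, 2L)
  expect_equal(rep$genes$mean_per_chromosome, 0) # 2/24 rounds to 0
  expect_equal(rep$genes$length$median, 550)
  expect_equal(rep$genes$length$total, 1100)
  expect_equal(rep$genes$length$sd, sd(c(500, 600)))
  expect_equal(rep$mrnas$n, 3L)
  expect_equal(rep$mrnas$length$total, 800)
  expect_equal(rep$mrnas$utr5$total, 150)
  expect_equal(rep$mrnas$cds$total, 500)
  expect_equal(rep$mrnas$utr3$total, 150)
  expect_equal(rep$exons$raw$n, 7L)
  expect_equal(rep$exons$raw$length$total, 800) # conserves mRNA total
  expect_equal(rep$exons$raw$length$max, 200)
  expect_equal(rep$exons$raw$length$max_label, "BETA, E2")
  expect_equal(rep$exons$raw$not_last$n, 4L)
  expect_equal(rep$exons$raw$not_last$mean, 100)
  expect_equal(rep$exons$nonredundant$n, 5L)
  expect_equal(rep$exons$nonredundant$length$total, 600)
  expect_equal(rep$exons$nonredundant$not_last$n, 3L)
  expect_equal(rep$coding_exons$raw$n, 7L)
  expect_equal(rep$coding_exons$raw$length$total, 500)
  expect_equal(rep$coding_exons$raw$length$min, 50)
  expect_equal(rep$coding_exons$raw$not_last$n, 4L)
  expect_equal(rep$coding_exons$raw$not_last$total, 250)
  expect_equal(rep$coding_exons$nonredundant$n, 5L)
  expect_equal(rep$coding_exons$nonredundant$length$total, 400)
  expect_equal(rep$introns$raw$n, 4L)
  expect_equal(rep$introns$raw$length$total, 800)
  expect_equal(rep$introns$raw$length$median, 200)
  expect_equal(rep$introns$nonredundant$n, 4L)
  expect_equal(rep$introns$raw$per_transcript$min, 1)
  expect_equal(rep$exons$raw$per_transcript$mean, 7 / 3)
})

test_that("the two mean paths agree on every value list", {
  for (seed in 1:20) {
    set.seed(seed)
    v <- sample(1:100000, sample(2:50, 1), replace = TRUE)
    expect_equal(mean_from_totals(sum(v), length(v), 6),
                 round_half_away(summarize_values(v)$mean, 6))
  }
})

test_that("comparing a report with itself gives zero deltas", {
  rep <- build_report(tiny_set())
  cmp <- compare_reports(rep, rep)
  expect_true(all(cmp$status == "ok"))
  ok <- !is.na(cmp$delta)
  expect_true(all(cmp$delta[ok] == 0))
  expect_true(all(cmp$pct_change[!is.na(cmp$pct_change)] == 0))
})

test_that("release comparison reproduces known gene-count growth", {
  # 18,255 -> 19,116 genes across the 2016 -> 2019 releases: +4.7%
  expect_equal(percent_change(18255, 19116), 4.7)
  gen1 <- generate_annotation(generator_params(n_genes = 30, seed = 1))
  gen2 <- generate_annotation(generator_params(n_genes = 45, seed = 2))
  r1 <- build_report(apply_curation(gen1$set)$set)
  r2 <- build_report(apply_curation(gen2$set)$set)
  cmp <- compare_reports(r1, r2)
  row <- cmp[cmp$metric == "genes.n", ]
  expect_equal(row$delta, r2$genes$n - r1$genes$n)
  expect_equal(row$pct_change,
               percent_change(r1$genes$n, r2$genes$n))
})
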