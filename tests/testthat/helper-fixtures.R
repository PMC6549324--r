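# Shared fixtures and property-test helpers. Everything is built in code;
# no files are read from disk except those the tests themselves write.

# Two-gene, three-transcript set with hand-checkable feature arithmetic:
# gene ALPHA (+, chr1) has two isoforms sharing exon coordinates; gene BETA
# (-, chrX) exercises minus-strand UTR/intron orientation.
tiny_set <- function() {
  genes <- data.frame(
    gene_id = c("1001", "1002"),
    symbol = c("ALPHA", "BETA"),
    chromosome = c("1", "X"),
    chrom_accession = c("NC_000001.11", "NC_000023.11"),
    strand = c("+", "-"),
    gene_start = c(1000L, 2000L),
    gene_end = c(1499L, 2599L),
    gene_type = "protein-coding",
    gene_refseq_status = "REVIEWED",
    in_current_annotation = TRUE,
    live_status = TRUE,
    stringsAsFactors = FALSE
  )
  transcripts <- data.frame(
    gene_id = c("1001", "1001", "1002"),
    accession = c("NM_000001.1", "NM_000002.1", "NM_000003.1"),
    transcript_refseq_status = c("REVIEWED", "VALIDATED", "REVIEWED"),
    protein_accession = c("NP_000001.1", "NP_000002.1", "NP_000003.1"),
    cds_start = c(1050L, 1050L, 2050L),
    cds_end = c(1449L, 1449L, 2549L),
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = c(rep("1001", 5), rep("1002", 2)),
    accession = c(rep("NM_000001.1", 3), rep("NM_000002.1", 2),
                  rep("NM_000003.1", 2)),
    exon_serial = c(1L, 2L, 3L, 1L, 2L, 1L, 2L),
    start = c(1000L, 1200L, 1400L, 1000L, 1400L, 2500L, 2000L),
    end = c(1099L, 1299L, 1499L, 1099L, 1499L, 2599L, 2199L),
    stringsAsFactors = FALSE
  )
  annotation_set(genes, transcripts, exons)
}

# random valid transcript_record for property tests (seeded)
random_transcript <- function(seed, coding = TRUE) {
  set.seed(seed)
  n <- sample(1:10, 1)
  lens <- sample(2:300, n, replace = TRUE)
  gaps <- if (n > 1) sample(30:2000, n - 1, replace = TRUE) else integer()
  strand <- sample(c("+", "-"), 1)
  g0 <- sample(10000:1000000, 1)
  starts <- integer(n); ends <- integer(n); pos <- g0
  for (k in seq_len(n)) {
    starts[k] <- pos; ends[k] <- pos + lens[k] - 1L
    pos <- ends[k] + (if (k < n) gaps[k] else 0L) + 1L
  }
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends) }
  t <- transcript_record(sprintf("NM_%06d.1", seed), "NC_000001.11", strand,
                         starts, ends)
  if (coding) {
    L <- sum(lens)
    u5 <- sample(0:(L - 2L), 1)
    cds <- sample(1:(L - u5 - 1L), 1)
    if (u5 + cds >= L) cds <- L - u5 - 1L
    g1 <- genefeatr:::mrna_pos_to_genomic(t, u5 + 1L)
    g2 <- genefeatr:::mrna_pos_to_genomic(t, u5 + cds)
    t$cds_start <- min(g1, g2)
    t$cds_end <- max(g1, g2)
    attr(t, "mrna_cds") <- c(u5 = u5, cds = cds, u3 = L - u5 - cds)
  }
  t
}

# mirror every coordinate of a transcript around a chromosome of length L
# (start' = L - end + 1) and flip the strand; transcription order and
# serials are unchanged.
mirror_transcript <- function(t, L = 10000000L) {
  transcript_record(
    t$accession, t$chrom_accession,
    if (t$strand == "+") "-" else "+",
    L - t$exon_ends + 1L, L - t$exon_starts + 1L,
    if (is.na(t$cds_start)) NA else L - t$cds_end + 1L,
    if (is.na(t$cds_start)) NA else L - t$cds_start + 1L,
    status = t$status
  )
}

mirror_set <- function(set, L = 10000000L) {
  g <- set$genes
  new_start <- L - g$gene_end + 1L
  g$gene_end <- L - g$gene_start + 1L
  g$gene_start <- new_start
  g$strand <- ifelse(g$strand == "+", "-", "+")
  tx <- set$transcripts
  cs <- L - tx$cds_end + 1L
  tx$cds_end <- L - tx$cds_start + 1L
  tx$cds_start <- cs
  ex <- set$exons
  es <- L - ex$end + 1L
  ex$end <- L - ex$start + 1L
  ex$start <- es
  annotation_set(g, tx, ex, provenance = set$provenance)
}

# compare two flattened report vectors: integer-valued cells exactly, real
# cells to 1e-9 relative; NA must match NA.
expect_reports_equal <- function(got, want, tol = 1e-9) {
  a <- flatten_report(got)
  b <- flatten_report(want)
  expect_setequal(names(a), names(b))
  b <- b[names(a)]
  both_na <- is.na(a) & is.na(b)
  expect_equal(is.na(a), is.na(b), info = "NA pattern differs")
  idx <- !both_na
  is_int <- idx & (b == floor(b)) & (a == floor(a))
  expect_identical(unname(a[is_int]), unname(b[is_int]))
  real <- idx & !is_int
  if (any(real)) {
    expect_lt(max(abs(a[real] - b[real]) / pmax(1, abs(b[real]))), tol)
  }
  invisible(TRUE)
}

# identical annotation-set contents (ignoring provenance)
expect_sets_equal <- function(x, y) {
  x <- genefeatr:::sort_annotation_set(x)
  y <- genefeatr:::sort_annotation_set(y)
  expect_equal(x$genes, y$genes)
  expect_equal(x$transcripts, y$transcripts)
  expect_equal(x$exons, y$exons)
  invisible(TRUE)
}
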