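# Derivation of gene features from transcript models: companion introns,
# coding-exon portions (stop codon included), UTR/CDS splits of the mRNA,
# last-exon flags, isoform non-redundancy labels and short-intron flags.

# Non-redundancy label constants ("Yes<em dash>Merged"/"Yes<em dash>Unique");
# blank means the row is a redundant duplicate of a labelled representative.
NR_UNIQUE <- "Yes\u2014Unique"
NR_MERGED <- "Yes\u2014Merged"

#' Derive the introns of one transcript
#'
#' Every transcript with n exons has exactly n - 1 introns; intron i fills
#' the genomic gap between exons i and i + 1 in transcription order, so on
#' the minus strand intron coordinates lie genomically left of their serial
#' predecessor's exon. Serial numbers follow transcription order.
#'
#' @param t A [transcript_record].
#' @return data.frame with columns `intron_serial`, `start`, `end`,
#'   `length`; zero rows for a mono-exonic transcript.
#' @export
derive_introns <- function(t) {
  n <- length(t$exon_starts)
  empty <- data.frame(intron_serial = integer(), start = integer(),
                      end = integer(), length = integer())
  if (n < 2L) return(empty)
  if (t$strand == "+") {
    start <- t$exon_ends[-n] + 1L
    end <- t$exon_starts[-1L] - 1L
  } else {
    start <- t$exon_ends[-1L] + 1L
    end <- t$exon_starts[-n] - 1L
  }
  if (any(start > end)) {
    stop(sprintf(
      "transcript %s: zero-length intron between adjacent exons (annotation defect)",
      t$accession
    ), call. = FALSE)
  }
  data.frame(
    intron_serial = seq_len(n - 1L),
    start = start, end = end,
    length = interval_length(start, end)
  )
}

#' Derive the coding portions of one transcript's exons
#'
#' The coding portion of an exon is its intersection with the genomic CDS
#' span (first to last coding base, stop codon included). Exons wholly
#' outside the CDS have no coding portion but still count among the
#' transcript's exons; coding serials number the non-empty portions in
#' transcription order. The portion lengths always sum to the CDS length.
#'
#' @param t A [transcript_record] with a CDS span.
#' @return data.frame with one row per exon that has a coding portion:
#'   `exon_serial`, `coding_serial`, `start`, `end`, `length`.
#' @export
derive_coding_exons <- function(t) {
  if (is.na(t$cds_start)) {
    stop(sprintf("transcript %s has no CDS; skip non-coding transcripts",
                 t$accession), call. = FALSE)
  }
  lo <- pmax(t$exon_starts, t$cds_start)
  hi <- pmin(t$exon_ends, t$cds_end)
  keep <- lo <= hi
  out <- data.frame(
    exon_serial = seq_along(t$exon_starts)[keep],
    coding_serial = cumsum(keep)[keep],
    start = lo[keep], end = hi[keep],
    length = hi[keep] - lo[keep] + 1L
  )
  rownames(out) <- NULL
  out
}

#' Partition an mRNA into 5' UTR, CDS and 3' UTR lengths
#'
#' Lengths are in mRNA (spliced) coordinates and always satisfy
#' `utr5 + cds + utr3 = transcript length`; the 5' and 3' sides are assigned
#' by strand, so a minus-strand transcript's 5' UTR lies genomically right
#' of its CDS.
#'
#' @param t A [transcript_record] with a CDS span covered by its exons.
#' @return Named list `utr5_len`, `cds_len`, `utr3_len`, `transcript_len`.
#' @export
split_utrs <- function(t) {
  exon_len <- interval_length(t$exon_starts, t$exon_ends)
  total <- sum(exon_len)
  if (is.na(t$cds_start)) {
    stop(sprintf("transcript %s has no CDS; skip non-coding transcripts",
                 t$accession), call. = FALSE)
  }
  lo <- min(t$exon_starts); hi <- max(t$exon_ends)
  if (t$cds_start < lo || t$cds_end > hi) {
    stop(sprintf("transcript %s: CDS span extends past exon union",
                 t$accession), call. = FALSE)
  }
  cds_len <- sum(pmax(
    0L, pmin(t$exon_ends, t$cds_end) - pmax(t$exon_starts, t$cds_start) + 1L
  ))
  # exonic bases strictly 5' of the first coding base, per strand
  if (t$strand == "+") {
    utr5 <- sum(pmax(0L, pmin(t$exon_ends, t$cds_start - 1L) - t$exon_starts + 1L))
  } else {
    utr5 <- sum(pmax(0L, t$exon_ends - pmax(t$exon_starts, t$cds_end + 1L) + 1L))
  }
  list(utr5_len = utr5, cds_len = cds_len,
       utr3_len = total - utr5 - cds_len, transcript_len = total)
}

#' Flag the last exon (and last coding exon) of a transcript
#'
#' Exactly one exon per transcript is the last: the 3'-most in transcription
#' order, i.e. the highest serial. For coding transcripts the analogous flag
#' marks the exon carrying the highest coding serial -- which can differ
#' from the last exon when the 3' UTR occupies one or more whole exons.
#'
#' @param t A [transcript_record].
#' @return List of two logical vectors (one entry per exon):
#'   `last_exon`, `last_coding_exon` (all `FALSE` when non-coding).
#' @export
flag_last_exons <- function(t) {
  n <- length(t$exon_starts)
  last <- seq_len(n) == n
  coding_last <- rep(FALSE, n)
  if (!is.na(t$cds_start)) {
    ce <- derive_coding_exons(t)
    if (nrow(ce)) {
      coding_last[ce$exon_serial[which.max(ce$coding_serial)]] <- TRUE
    }
  }
  list(last_exon = last, last_coding_exon = coding_last)
}

# genomic bounding span of the exonic bases 5' (utr5) or 3' (utr3) of the
# CDS; returns c(NA, NA) when the UTR is empty.
utr_genomic_span <- function(t, side = c("utr5", "utr3")) {
  side <- match.arg(side)
  five_prime_left <- (t$strand == "+") == (side == "utr5")
  if (five_prime_left) {
    lo <- pmax(t$exon_starts, 1L)
    hi <- pmin(t$exon_ends, t$cds_start - 1L)
  } else {
    lo <- pmax(t$exon_starts, t$cds_end + 1L)
    hi <- t$exon_ends
  }
  keep <- lo <= hi
  if (!any(keep)) return(c(NA_integer_, NA_integer_))
  c(min(lo[keep]), max(hi[keep]))
}

#' Build the per-exon feature table (one row per exon of every transcript)
#'
#' The long-format export behind all length statistics: each row describes
#' one exon of one transcript together with its coding portion (if any) and
#' its companion intron -- the intron immediately downstream of the exon in
#' transcription order. Last-exon rows therefore carry no intron data.
#' Non-redundancy labels for exons, coding portions and introns are applied
#' with [mark_non_redundant()].
#'
#' @param set An [annotation_set] (curated or not).
#' @return data.frame of feature rows in (gene_id, accession, exon_serial)
#'   order, with non-redundancy columns filled in.
#' @export
build_gene_table <- function(set) {
  set <- sort_annotation_set(set)
  recs <- set_transcript_records(set)
  g <- set$genes
  tx <- set$transcripts
  rows <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    t <- recs[[i]]
    n <- length(t$exon_starts)
    gi <- match(tx$gene_id[i], g$gene_id)
    exon_len <- interval_length(t$exon_starts, t$exon_ends)
    flags <- flag_last_exons(t)
    row <- data.frame(
      gene_id = tx$gene_id[i],
      symbol = g$symbol[gi],
      gene_type = g$gene_type[gi],
      chromosome = g$chromosome[gi],
      chrom_accession = g$chrom_accession[gi],
      strand = g$strand[gi],
      gene_start = g$gene_start[gi],
      gene_end = g$gene_end[gi],
      gene_length = interval_length(g$gene_start[gi], g$gene_end[gi]),
      transcript_accession = t$accession,
      transcript_refseq_status = tx$transcript_refseq_status[i],
      transcript_length = sum(exon_len),
      utr5_start = NA_integer_, utr5_end = NA_integer_,
      utr5_length = NA_integer_,
      cds_start = tx$cds_start[i], cds_end = tx$cds_end[i],
      cds_length = NA_integer_,
      utr3_start = NA_integer_, utr3_end = NA_integer_,
      utr3_length = NA_integer_,
      exon_start = t$exon_starts, exon_end = t$exon_ends,
      exon_length = exon_len, exon_serial = seq_len(n),
      coding_start = NA_integer_, coding_end = NA_integer_,
      coding_length = NA_integer_, coding_serial = NA_integer_,
      intron_start = NA_integer_, intron_end = NA_integer_,
      intron_length = NA_integer_, intron_serial = NA_integer_,
      last_exon = flags$last_exon,
      last_coding_exon = flags$last_coding_exon,
      nr_exon = "", nr_coding = "", nr_intron = "",
      protein_accession = tx$protein_accession[i],
      live_status = g$live_status[gi],
      in_current_annotation = g$in_current_annotation[gi],
      gene_refseq_status = g$gene_refseq_status[gi],
      stringsAsFactors = FALSE
    )
    if (!is.na(t$cds_start)) {
      sp <- split_utrs(t)
      row$utr5_length <- sp$utr5_len
      row$cds_length <- sp$cds_len
      row$utr3_length <- sp$utr3_len
      u5 <- utr_genomic_span(t, "utr5")
      u3 <- utr_genomic_span(t, "utr3")
      row$utr5_start <- u5[1L]; row$utr5_end <- u5[2L]
      row$utr3_start <- u3[1L]; row$utr3_end <- u3[2L]
      ce <- derive_coding_exons(t)
      idx <- match(seq_len(n), ce$exon_serial)
      row$coding_start <- ce$start[idx]
      row$coding_end <- ce$end[idx]
      row$coding_length <- ce$length[idx]
      row$coding_serial <- ce$coding_serial[idx]
    }
    ins <- derive_introns(t)
    if (nrow(ins)) {
      # companion layout: intron i sits on the row of its upstream exon i
      row$intron_start[seq_len(n - 1L)] <- ins$start
      row$intron_end[seq_len(n - 1L)] <- ins$end
      row$intron_length[seq_len(n - 1L)] <- ins$length
      row$intron_serial[seq_len(n - 1L)] <- ins$intron_serial
    }
    rows[[i]] <- row
  }
  gt <- if (length(rows)) do.call(rbind, rows) else empty_gene_table()
  rownames(gt) <- NULL
  for (fc in c("exon", "coding", "intron")) gt <- mark_non_redundant(gt, fc)
  gt
}

empty_gene_table <- function() {
  build_gene_table_cols <- c(
    "gene_id", "symbol", "gene_type", "chromosome", "chrom_accession",
    "strand", "gene_start", "gene_end", "gene_length",
    "transcript_accession", "transcript_refseq_status", "transcript_length",
    "utr5_start", "utr5_end", "utr5_length",
    "cds_start", "cds_end", "cds_length",
    "utr3_start", "utr3_end", "utr3_length",
    "exon_start", "exon_end", "exon_length", "exon_serial",
    "coding_start", "coding_end", "coding_length", "coding_serial",
    "intron_start", "intron_end", "intron_length", "intron_serial",
    "last_exon", "last_coding_exon", "nr_exon", "nr_coding", "nr_intron",
    "protein_accession", "live_status", "in_current_annotation",
    "gene_refseq_status"
  )
  proto <- function(nm) {
    if (nm %in% c("last_exon", "last_coding_exon", "live_status",
                  "in_current_annotation")) return(logical(0))
    if (grepl("_(start|end|length|serial)$", nm) || nm == "transcript_length") {
      return(integer(0))
    }
    character(0)
  }
  as.data.frame(
    setNames(lapply(build_gene_table_cols, proto), build_gene_table_cols),
    stringsAsFactors = FALSE
  )
}

#' Label one representative per group of identical features
#'
#' Exons, coding portions and introns shared by several transcript isoforms
#' appear as several identical-coordinate rows of the feature table.
#' Identity is exact coordinate equality scoped per feature class,
#' chromosome accession and strand. Within each identity group exactly one
#' row -- the first under the deterministic (gene_id, transcript accession,
#' serial) sort -- is labelled: `"Yes—Unique"` when the group has a single
#' member, `"Yes—Merged"` when the element recurs; all other rows stay
#' blank. Filtering for non-blank labels yields the non-redundant feature
#' set.
#'
#' @param gt Feature table from [build_gene_table()].
#' @param feature_class One of `"exon"`, `"coding"`, `"intron"`.
#' @return `gt` with the corresponding `nr_*` column filled.
#' @export
mark_non_redundant <- function(gt, feature_class = c("exon", "coding", "intron")) {
  feature_class <- match.arg(feature_class)
  scol <- paste0(feature_class, "_start")
  ecol <- paste0(feature_class, "_end")
  srl <- paste0(feature_class, "_serial")
  ncol <- switch(feature_class, exon = "nr_exon", coding = "nr_coding",
                 intron = "nr_intron")
  gt[[ncol]] <- character(nrow(gt))
  has <- !is.na(gt[[scol]])
  if (!any(has)) return(gt)
  idx <- which(has)
  key <- paste(gt$chrom_accession[idx], gt$strand[idx],
               gt[[scol]][idx], gt[[ecol]][idx], sep = "\r")
  ord <- order(gt$gene_id[idx], gt$transcript_accession[idx], gt[[srl]][idx])
  idx_sorted <- idx[ord]
  key_sorted <- key[ord]
  first <- !duplicated(key_sorted)
  sizes <- table(key_sorted)
  label <- ifelse(sizes[key_sorted[first]] > 1L, NR_MERGED, NR_UNIQUE)
  gt[[ncol]][idx_sorted[first]] <- label
  gt
}

#' Report non-redundant introns shorter than a threshold
#'
#' Human introns excised by canonical splicing are never shorter than 30 bp;
#' shorter values in annotation-derived tables are either parsing artifacts
#' (typically 1-3 bp) or non-canonical excision events such as the
#' IRE1-mediated 26-bp removal in XBP1. This flags candidates for manual
#' review; nothing is removed automatically.
#'
#' @param gt Feature table from [build_gene_table()].
#' @param threshold Length threshold in bp (default 30); introns with
#'   `length < threshold` are reported.
#' @return data.frame of flagged non-redundant introns with columns
#'   `symbol`, `transcript_accession`, `intron_serial`, `start`, `end`,
#'   `length`, `category` (`"likely_artifact"` for 1-3 bp, otherwise
#'   `"non_canonical_excision_candidate"`).
#' @export
flag_short_introns <- function(gt, threshold = 30L) {
  keep <- !is.na(gt$intron_length) & gt$nr_intron != "" &
    gt$intron_length < threshold
  out <- gt[keep, c("symbol", "transcript_accession", "intron_serial",
                    "intron_start", "intron_end", "intron_length")]
  names(out) <- c("symbol", "transcript_accession", "intron_serial",
                  "start", "end", "length")
  out$category <- ifelse(out$length <= 3L, "likely_artifact",
                         "non_canonical_excision_candidate")
  rownames(out) <- NULL
  out[order(out$length, out$symbol), , drop = FALSE]
}

#' Per-transcript structural summaries
#'
#' @param set An [annotation_set].
#' @return data.frame with one row per transcript: exon/coding-exon/intron
#'   counts and transcript/UTR5/CDS/UTR3 lengths (`NA` UTR/CDS columns for
#'   non-coding transcripts).
#' @export
transcript_summaries <- function(set) {
  recs <- set_transcript_records(set)
  tx <- set$transcripts
  n <- length(recs)
  out <- data.frame(
    gene_id = tx$gene_id, accession = tx$accession,
    n_exons = integer(n), n_coding_exons = rep(NA_integer_, n),
    n_introns = integer(n), transcript_len = integer(n),
    utr5_len = rep(NA_integer_, n), cds_len = rep(NA_integer_, n),
    utr3_len = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(recs)) {
    t <- recs[[i]]
    out$n_exons[i] <- length(t$exon_starts)
    out$n_introns[i] <- out$n_exons[i] - 1L
    out$transcript_len[i] <- sum(interval_length(t$exon_starts, t$exon_ends))
    if (!is.na(t$cds_start)) {
      sp <- split_utrs(t)
      out$utr5_len[i] <- sp$utr5_len
      out$cds_len[i] <- sp$cds_len
      out$utr3_len[i] <- sp$utr3_len
      out$n_coding_exons[i] <- nrow(derive_coding_exons(t))
    }
  }
  out
}
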