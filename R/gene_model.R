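# Core domain model: genomic intervals, gene/transcript/exon tables, and the
# coordinate arithmetic shared by every later stage.
#
# Conventions (fixed throughout the package):
#   * coordinates are 1-based and inclusive at both ends (NCBI / GFF3 / GTF);
#   * intervals are stored genomically (start <= end) regardless of strand;
#     transcription order is carried by serial numbers, never by coordinate
#     order, so minus-strand models are unambiguous;
#   * chromosome names are text everywhere ("1".."22", "X", "Y", "MT"), never
#     numeric, so "X"/"Y" cannot be coerced to numbers downstream.

#' Length of a 1-based inclusive genomic interval
#'
#' @param start,end Integer vectors of 1-based inclusive coordinates.
#' @return Integer vector of lengths in bp (`end - start + 1`).
#' @examples
#' interval_length(101, 200) # 100
#' interval_length(5, 5)     # 1
#' @export
interval_length <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start) | is.na(end))) {
    stop("invalid interval: NA coordinate", call. = FALSE)
  }
  if (any(start < 1L)) {
    stop("invalid interval: start < 1", call. = FALSE)
  }
  if (any(start > end)) {
    stop("invalid interval: start > end", call. = FALSE)
  }
  end - start + 1L
}

#' Construct a single-transcript record
#'
#' A lightweight container for one mRNA: its exons in transcription
#' (5'->3') order and, when coding, the genomic CDS span (first to last
#' coding base, stop codon included).
#'
#' @param accession Transcript accession (e.g. `"NM_000001.1"`).
#' @param chrom_accession Chromosome sequence accession.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors, one entry per exon, in
#'   transcription order; each exon stored genomically (start <= end).
#' @param cds_start,cds_end Genomic CDS span (stop codon included), or `NA`
#'   for a non-coding transcript.
#' @param status RefSeq status of the transcript.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `transcript_record`.
#' @export
transcript_record <- function(accession, chrom_accession, strand,
                              exon_starts, exon_ends,
                              cds_start = NA, cds_end = NA,
                              status = NA_character_, validate = TRUE) {
  t <- structure(
    list(
      accession = as.character(accession),
      chrom_accession = as.character(chrom_accession),
      strand = as.character(strand),
      exon_starts = as.integer(exon_starts),
      exon_ends = as.integer(exon_ends),
      cds_start = as.integer(cds_start),
      cds_end = as.integer(cds_end),
      status = as.character(status)
    ),
    class = "transcript_record"
  )
  if (validate) validate_transcript(t)
  t
}

#' @export
print.transcript_record <- function(x, ...) {
  n <- length(x$exon_starts)
  cat(sprintf(
    "<transcript_record> %s [%s%s] %d exon(s), %s\n",
    x$accession, x$chrom_accession, x$strand, n,
    if (is.na(x$cds_start)) "non-coding" else
      sprintf("CDS %d-%d", x$cds_start, x$cds_end)
  ))
  invisible(x)
}

# Validate one transcript's structural invariants; stops with a labelled
# error on the first violation.
validate_transcript <- function(t) {
  n <- length(t$exon_starts)
  if (n < 1L) {
    stop(sprintf("transcript %s: no exons", t$accession), call. = FALSE)
  }
  if (length(t$exon_ends) != n) {
    stop(sprintf("transcript %s: exon start/end length mismatch", t$accession),
         call. = FALSE)
  }
  if (!t$strand %in% c("+", "-")) {
    stop(sprintf("transcript %s: strand must be '+' or '-'", t$accession),
         call. = FALSE)
  }
  interval_length(t$exon_starts, t$exon_ends) # validates start <= end etc.
  if (n > 1L) {
    if (t$strand == "+") {
      gaps <- t$exon_starts[-1L] - t$exon_ends[-n] - 1L
    } else {
      gaps <- t$exon_starts[-n] - t$exon_ends[-1L] - 1L
    }
    if (any(gaps < 0L)) {
      stop(sprintf(
        "transcript %s: exons overlap or are out of transcription order",
        t$accession
      ), call. = FALSE)
    }
    if (any(gaps == 0L)) {
      stop(sprintf(
        "transcript %s: zero-length intron between adjacent exons (annotation defect)",
        t$accession
      ), call. = FALSE)
    }
  }
  if (!is.na(t$cds_start)) {
    if (is.na(t$cds_end) || t$cds_start > t$cds_end) {
      stop(sprintf("transcript %s: invalid CDS span", t$accession),
           call. = FALSE)
    }
    # CDS first and last bases must fall inside exons, and the span must not
    # poke past the exon union.
    lo <- min(t$exon_starts); hi <- max(t$exon_ends)
    inside <- function(p) any(p >= t$exon_starts & p <= t$exon_ends)
    if (t$cds_start < lo || t$cds_end > hi ||
        !inside(t$cds_start) || !inside(t$cds_end)) {
      stop(sprintf(
        "transcript %s: CDS span not covered by exons", t$accession
      ), call. = FALSE)
    }
  }
  invisible(t)
}

#' Union span of a set of transcripts
#'
#' Backstop for input formats lacking an explicit gene feature: the gene
#' span is the min-start/max-end union over all exons of all transcripts.
#' Multi-chromosome or multi-strand gene models are rejected (trans-splicing
#' is outside this data model).
#'
#' @param transcripts List of [transcript_record] objects.
#' @return List with `chrom_accession`, `strand`, `start`, `end`.
#' @export
gene_span_from_transcripts <- function(transcripts) {
  if (length(transcripts) < 1L) {
    stop("gene span requires at least one transcript", call. = FALSE)
  }
  chroms <- unique(vapply(transcripts, `[[`, "", "chrom_accession"))
  strands <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chroms) > 1L || length(strands) > 1L) {
    stop("trans-splicing unsupported: transcripts span multiple chromosomes or strands",
         call. = FALSE)
  }
  list(
    chrom_accession = chroms,
    strand = strands,
    start = min(vapply(transcripts, function(t) min(t$exon_starts), 1L)),
    end = max(vapply(transcripts, function(t) max(t$exon_ends), 1L))
  )
}

# ---- annotation_set -------------------------------------------------------

GENE_COLS <- c(
  "gene_id", "symbol", "chromosome", "chrom_accession", "strand",
  "gene_start", "gene_end", "gene_type", "gene_refseq_status",
  "in_current_annotation", "live_status"
)
TX_COLS <- c(
  "gene_id", "accession", "transcript_refseq_status", "protein_accession",
  "cds_start", "cds_end"
)
EXON_COLS <- c("gene_id", "accession", "exon_serial", "start", "end")

#' Construct an annotation set
#'
#' The in-memory container for one imported annotation release: three keyed
#' data frames (genes, transcripts, exons) mirroring the gene -> mRNA -> exon
#' hierarchy. Exon rows are kept in transcription order per transcript and
#' numbered by `exon_serial` starting at 1.
#'
#' @param genes data.frame with columns `gene_id`, `symbol`, `chromosome`,
#'   `chrom_accession`, `strand`, `gene_start`, `gene_end`, `gene_type`,
#'   `gene_refseq_status`, `in_current_annotation`, `live_status`.
#' @param transcripts data.frame with columns `gene_id`, `accession`,
#'   `transcript_refseq_status`, `protein_accession`, `cds_start`, `cds_end`
#'   (CDS columns `NA` for non-coding transcripts; span includes the stop
#'   codon).
#' @param exons data.frame with columns `gene_id`, `accession`,
#'   `exon_serial`, `start`, `end`.
#' @param provenance Optional list recording source format and path.
#' @param validate Check all structural invariants (default `TRUE`).
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(genes, transcripts, exons,
                           provenance = list(), validate = TRUE) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  for (cc in list(c("genes", GENE_COLS), c("transcripts", TX_COLS),
                  c("exons", EXON_COLS))) {
    tab <- get(cc[1L])
    miss <- setdiff(cc[-1L], names(tab))
    if (length(miss)) {
      stop(sprintf("%s table lacks column(s): %s", cc[1L],
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  genes <- genes[GENE_COLS]
  transcripts <- transcripts[TX_COLS]
  exons <- exons[EXON_COLS]
  int_cols <- function(df, cols) {
    for (cl in cols) df[[cl]] <- as.integer(df[[cl]])
    df
  }
  genes <- int_cols(genes, c("gene_start", "gene_end"))
  genes$chromosome <- as.character(genes$chromosome)
  genes$in_current_annotation <- as.logical(genes$in_current_annotation)
  genes$live_status <- as.logical(genes$live_status)
  transcripts <- int_cols(transcripts, c("cds_start", "cds_end"))
  exons <- int_cols(exons, c("exon_serial", "start", "end"))
  set <- structure(
    list(genes = genes, transcripts = transcripts, exons = exons,
         provenance = provenance),
    class = "annotation_set"
  )
  if (validate) validate_annotation_set(set)
  set
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %d gene(s), %d transcript(s), %d exon row(s)\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons)
  ))
  if (!is.null(x$provenance$source_format)) {
    cat(sprintf("  source: %s (%s)\n",
                x$provenance$source_path %||% "<memory>",
                x$provenance$source_format))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an annotation set
#'
#' Checks every structural invariant of the model: unique gene identifiers,
#' resolvable gene/transcript keys, per-transcript exon ordering and gap
#' invariants, CDS coverage, and gene spans covering their transcripts.
#'
#' @param set An [annotation_set].
#' @return Invisibly, `set`; stops on the first violation.
#' @export
validate_annotation_set <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  g <- set$genes
  if (anyDuplicated(g$gene_id)) {
    stop("duplicate gene_id in annotation set", call. = FALSE)
  }
  if (nrow(set$transcripts)) {
    if (anyDuplicated(set$transcripts$accession)) {
      stop("duplicate transcript accession in annotation set", call. = FALSE)
    }
    orphan <- setdiff(set$transcripts$gene_id, g$gene_id)
    if (length(orphan)) {
      stop(sprintf("transcript(s) reference unknown gene_id: %s",
                   paste(head(orphan, 3L), collapse = ", ")), call. = FALSE)
    }
  }
  if (nrow(set$exons)) {
    orphan <- setdiff(set$exons$accession, set$transcripts$accession)
    if (length(orphan)) {
      stop(sprintf("exon row(s) reference unknown transcript: %s",
                   paste(head(orphan, 3L), collapse = ", ")), call. = FALSE)
    }
  }
  if (nrow(g)) interval_length(g$gene_start, g$gene_end)
  for (t in set_transcript_records(set)) validate_transcript(t)
  # gene span must cover the union of its transcripts' exons
  if (nrow(set$exons)) {
    lo <- tapply(set$exons$start, set$exons$gene_id, min)
    hi <- tapply(set$exons$end, set$exons$gene_id, max)
    idx <- match(names(lo), g$gene_id)
    bad <- g$gene_start[idx] > lo | g$gene_end[idx] < hi
    if (any(bad)) {
      stop(sprintf("gene span does not cover transcripts for: %s",
                   paste(head(names(lo)[bad], 3L), collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(set)
}

#' Extract per-transcript records from an annotation set
#'
#' @param set An [annotation_set].
#' @return Named list of [transcript_record] objects (names = accessions),
#'   in the transcripts-table row order.
#' @export
set_transcript_records <- function(set) {
  tx <- set$transcripts
  if (!nrow(tx)) return(structure(list(), names = character()))
  g <- set$genes
  gi <- match(tx$gene_id, g$gene_id)
  ex_split <- split(set$exons[c("exon_serial", "start", "end")],
                    factor(set$exons$accession, levels = tx$accession))
  out <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    ex <- ex_split[[i]]
    ex <- ex[order(ex$exon_serial), , drop = FALSE]
    out[[i]] <- transcript_record(
      accession = tx$accession[i],
      chrom_accession = g$chrom_accession[gi[i]],
      strand = g$strand[gi[i]],
      exon_starts = ex$start, exon_ends = ex$end,
      cds_start = tx$cds_start[i], cds_end = tx$cds_end[i],
      status = tx$transcript_refseq_status[i],
      validate = FALSE
    )
  }
  names(out) <- tx$accession
  out
}

# Map an mRNA (spliced, 1-based, transcription-order) position to its
# genomic coordinate on a transcript.
mrna_pos_to_genomic <- function(t, pos) {
  lens <- t$exon_ends - t$exon_starts + 1L
  cum <- cumsum(lens)
  if (pos < 1L || pos > cum[length(cum)]) {
    stop(sprintf("mRNA position %d outside transcript %s", pos, t$accession),
         call. = FALSE)
  }
  i <- which(pos <= cum)[1L]
  off <- pos - c(0L, cum)[i]
  if (t$strand == "+") t$exon_starts[i] + off - 1L
  else t$exon_ends[i] - off + 1L
}

# Map an mRNA coordinate range to its genomic segments (one per exon it
# touches), in transcription order; each segment stored genomically.
mrna_range_to_segments <- function(t, m_lo, m_hi) {
  lens <- t$exon_ends - t$exon_starts + 1L
  cum <- cumsum(lens)
  before <- c(0L, cum[-length(cum)])
  out_start <- integer(); out_end <- integer()
  for (i in seq_along(lens)) {
    olo <- max(m_lo, before[i] + 1L)
    ohi <- min(m_hi, cum[i])
    if (olo > ohi) next
    if (t$strand == "+") {
      gs <- t$exon_starts[i] + (olo - before[i]) - 1L
      ge <- t$exon_starts[i] + (ohi - before[i]) - 1L
    } else {
      ge <- t$exon_ends[i] - (olo - before[i]) + 1L
      gs <- t$exon_ends[i] - (ohi - before[i]) + 1L
    }
    out_start <- c(out_start, gs)
    out_end <- c(out_end, ge)
  }
  data.frame(start = out_start, end = out_end)
}

# Canonical row ordering used by the table writers: genes by gene_id,
# transcripts by (gene_id, accession), exons by (gene_id, accession, serial).
sort_annotation_set <- function(set) {
  set$genes <- set$genes[order(set$genes$gene_id), , drop = FALSE]
  set$transcripts <- set$transcripts[
    order(set$transcripts$gene_id, set$transcripts$accession), , drop = FALSE]
  set$exons <- set$exons[
    order(set$exons$gene_id, set$exons$accession, set$exons$exon_serial), ,
    drop = FALSE]
  rownames(set$genes) <- rownames(set$transcripts) <- rownames(set$exons) <- NULL
  set
}
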