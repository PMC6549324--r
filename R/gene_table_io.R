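# The three-table TSV export dialect: Genes, Transcripts and the per-exon
# feature table (Gene_Table). UTF-8, Unix newlines, tab-separated, header in
# the first row; chromosome always text; absent intron/coding cells are
# empty strings, never 0 (0 would look like a valid length). Column meanings
# are documented in inst/extdata/data_dictionary.tsv.

GENES_TSV_COLS <- c(
  "GeneID", "Gene_Symbol", "Chromosome", "Gene_Type", "Gene_RefSeq_Status",
  "Transcript_RefSeq_Statuses", "Gene_Length_bp"
)
TRANSCRIPTS_TSV_COLS <- c(
  "GeneID", "Gene_Symbol", "Chromosome", "Gene_Type", "Gene_RefSeq_Status",
  "Transcript_Accession", "Transcript_RefSeq_Status", "Transcript_Length_bp",
  "UTR5_Length_bp", "CDS_Length_bp", "UTR3_Length_bp",
  "Exon_Count", "Coding_Exon_Count"
)
GENE_TABLE_TSV_COLS <- c(
  "GeneID", "Gene_Symbol", "Gene_Type", "Chromosome", "Chromosome_Accession",
  "Strand", "Gene_Start", "Gene_End", "Gene_Length_bp",
  "Transcript_Accession", "Transcript_RefSeq_Status", "Transcript_Length_bp",
  "UTR5_Start", "UTR5_End", "UTR5_Length_bp",
  "CDS_Start", "CDS_End", "CDS_Length_bp",
  "UTR3_Start", "UTR3_End", "UTR3_Length_bp",
  "Exon_Start", "Exon_End", "Exon_Length_bp", "Exon_Serial",
  "Coding_Start", "Coding_End", "Coding_Length_bp", "Coding_Serial",
  "Intron_Start", "Intron_End", "Intron_Length_bp", "Intron_Serial",
  "Last_Exon", "Last_Coding_Exon",
  "Non_Redundant_Exon", "Non_Redundant_Coding_Exon", "Non_Redundant_Intron",
  "Protein_Accession", "Live_Status", "Genome_Annotation_Status",
  "Gene_RefSeq_Status"
)

cell <- function(x) {
  out <- as.character(x)
  out[is.na(out)] <- ""
  out
}
yes_cell <- function(x) ifelse(!is.na(x) & x, "Yes", "")

write_tsv_table <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n",
             useBytes = TRUE)
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, cell), sep = "\t"))
    writeLines(enc2utf8(body), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Write the Genes table
#'
#' One row per gene: identifiers, chromosome (as text), type, RefSeq
#' statuses (the gene's own plus the distinct statuses of its transcripts)
#' and gene length in bp.
#'
#' @param set An [annotation_set].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_genes_table <- function(set, path) {
  set <- sort_annotation_set(set)
  g <- set$genes
  tx_status <- vapply(g$gene_id, function(gid) {
    st <- sort(unique(set$transcripts$transcript_refseq_status[
      set$transcripts$gene_id == gid]))
    paste(st, collapse = "; ")
  }, "")
  df <- data.frame(
    GeneID = g$gene_id,
    Gene_Symbol = g$symbol,
    Chromosome = g$chromosome,
    Gene_Type = g$gene_type,
    Gene_RefSeq_Status = g$gene_refseq_status,
    Transcript_RefSeq_Statuses = tx_status,
    Gene_Length_bp = if (nrow(g)) interval_length(g$gene_start, g$gene_end)
      else integer(),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  write_tsv_table(df[GENES_TSV_COLS], path)
}

#' Write the Transcripts table
#'
#' One row per transcript: whole-transcript, 5' UTR, CDS and 3' UTR lengths
#' in bp plus exon and coding-exon counts (UTR/CDS cells empty for
#' non-coding transcripts).
#'
#' @inheritParams write_genes_table
#' @return Invisibly, `path`.
#' @export
write_transcripts_table <- function(set, path) {
  set <- sort_annotation_set(set)
  ts <- transcript_summaries(set)
  g <- set$genes
  gi <- match(ts$gene_id, g$gene_id)
  ti <- match(ts$accession, set$transcripts$accession)
  df <- data.frame(
    GeneID = ts$gene_id,
    Gene_Symbol = g$symbol[gi],
    Chromosome = g$chromosome[gi],
    Gene_Type = g$gene_type[gi],
    Gene_RefSeq_Status = g$gene_refseq_status[gi],
    Transcript_Accession = ts$accession,
    Transcript_RefSeq_Status =
      set$transcripts$transcript_refseq_status[ti],
    Transcript_Length_bp = ts$transcript_len,
    UTR5_Length_bp = ts$utr5_len,
    CDS_Length_bp = ts$cds_len,
    UTR3_Length_bp = ts$utr3_len,
    Exon_Count = ts$n_exons,
    Coding_Exon_Count = ts$n_coding_exons,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  write_tsv_table(df[TRANSCRIPTS_TSV_COLS], path)
}

# internal: feature table data.frame -> export data.frame (dialect columns)
gene_table_export_df <- function(gt) {
  data.frame(
    GeneID = gt$gene_id,
    Gene_Symbol = gt$symbol,
    Gene_Type = gt$gene_type,
    Chromosome = gt$chromosome,
    Chromosome_Accession = gt$chrom_accession,
    Strand = gt$strand,
    Gene_Start = gt$gene_start, Gene_End = gt$gene_end,
    Gene_Length_bp = gt$gene_length,
    Transcript_Accession = gt$transcript_accession,
    Transcript_RefSeq_Status = gt$transcript_refseq_status,
    Transcript_Length_bp = gt$transcript_length,
    UTR5_Start = gt$utr5_start, UTR5_End = gt$utr5_end,
    UTR5_Length_bp = gt$utr5_length,
    CDS_Start = gt$cds_start, CDS_End = gt$cds_end,
    CDS_Length_bp = gt$cds_length,
    UTR3_Start = gt$utr3_start, UTR3_End = gt$utr3_end,
    UTR3_Length_bp = gt$utr3_length,
    Exon_Start = gt$exon_start, Exon_End = gt$exon_end,
    Exon_Length_bp = gt$exon_length, Exon_Serial = gt$exon_serial,
    Coding_Start = gt$coding_start, Coding_End = gt$coding_end,
    Coding_Length_bp = gt$coding_length, Coding_Serial = gt$coding_serial,
    Intron_Start = gt$intron_start, Intron_End = gt$intron_end,
    Intron_Length_bp = gt$intron_length, Intron_Serial = gt$intron_serial,
    Last_Exon = yes_cell(gt$last_exon),
    Last_Coding_Exon = yes_cell(gt$last_coding_exon),
    Non_Redundant_Exon = gt$nr_exon,
    Non_Redundant_Coding_Exon = gt$nr_coding,
    Non_Redundant_Intron = gt$nr_intron,
    Protein_Accession = gt$protein_accession,
    Live_Status = ifelse(gt$live_status, "live", "discontinued"),
    Genome_Annotation_Status = ifelse(
      gt$in_current_annotation, "current", "not in current annotation release"
    ),
    Gene_RefSeq_Status = gt$gene_refseq_status,
    stringsAsFactors = FALSE, check.names = FALSE
  )
}

#' Write the per-exon feature table (Gene_Table)
#'
#' One row per exon of every transcript, with its coding portion, its
#' companion intron (absent on last-exon rows), last-exon flags and
#' non-redundancy labels. Derivation runs automatically when an
#' [annotation_set] is given; a precomputed table from [build_gene_table()]
#' is accepted too.
#'
#' @param x An [annotation_set] or a feature table from
#'   [build_gene_table()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_gene_table <- function(x, path) {
  gt <- if (inherits(x, "annotation_set")) build_gene_table(x) else x
  needed <- c("nr_exon", "nr_coding", "nr_intron", "last_exon")
  if (!all(needed %in% names(gt))) {
    stop("input lacks derived feature columns; run build_gene_table() first",
         call. = FALSE)
  }
  write_tsv_table(gene_table_export_df(gt)[GENE_TABLE_TSV_COLS], path)
}

int_or_na <- function(x) {
  out <- suppressWarnings(as.integer(x))
  out[!is.na(x) & x == ""] <- NA_integer_
  out
}

#' Read the per-exon feature table dialect back into an annotation set
#'
#' Reconstructs gene, transcript and exon records from a Gene_Table TSV
#' written by [write_gene_table()], then re-derives every computed column
#' (intron/coding coordinates, UTR/CDS lengths, serials, flags,
#' non-redundancy labels) from the reconstructed exons and checks the file
#' against its own re-derivation: any stated length that disagrees with
#' `end - start + 1`, or any derived cell that cannot be reproduced, raises
#' an integrity error naming the offending row.
#'
#' @param path Path to a Gene_Table TSV.
#' @param check Re-derive and verify every computed column (default `TRUE`).
#' @return An [annotation_set].
#' @export
read_gene_table <- function(path, check = TRUE) {
  df <- read.delim(path, sep = "\t", colClasses = "character",
                   check.names = FALSE, quote = "", encoding = "UTF-8")
  miss <- setdiff(GENE_TABLE_TSV_COLS, names(df))
  if (length(miss)) {
    stop(sprintf("gene table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  # row-level integrity: stated lengths must match coordinates
  for (feat in c("Gene", "Exon", "Coding", "Intron")) {
    s <- int_or_na(df[[paste0(feat, "_Start")]])
    e <- int_or_na(df[[paste0(feat, "_End")]])
    l <- int_or_na(df[[paste0(feat, "_Length_bp")]])
    has <- !is.na(s)
    bad <- has & (is.na(l) | l != e - s + 1L)
    if (any(bad)) {
      stop(sprintf(
        "integrity error: %s length disagrees with coordinates at data row %d",
        tolower(feat), which(bad)[1L]
      ), call. = FALSE)
    }
  }
  g_first <- !duplicated(df$GeneID)
  genes <- data.frame(
    gene_id = df$GeneID[g_first],
    symbol = df$Gene_Symbol[g_first],
    chromosome = df$Chromosome[g_first],
    chrom_accession = df$Chromosome_Accession[g_first],
    strand = df$Strand[g_first],
    gene_start = int_or_na(df$Gene_Start[g_first]),
    gene_end = int_or_na(df$Gene_End[g_first]),
    gene_type = df$Gene_Type[g_first],
    gene_refseq_status = df$Gene_RefSeq_Status[g_first],
    in_current_annotation = df$Genome_Annotation_Status[g_first] == "current",
    live_status = df$Live_Status[g_first] == "live",
    stringsAsFactors = FALSE
  )
  t_first <- !duplicated(df$Transcript_Accession)
  cds_s <- int_or_na(df$CDS_Start)
  cds_e <- int_or_na(df$CDS_End)
  prot <- df$Protein_Accession
  prot[prot == ""] <- NA_character_
  transcripts <- data.frame(
    gene_id = df$GeneID[t_first],
    accession = df$Transcript_Accession[t_first],
    transcript_refseq_status = df$Transcript_RefSeq_Status[t_first],
    protein_accession = prot[t_first],
    cds_start = cds_s[t_first],
    cds_end = cds_e[t_first],
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = df$GeneID,
    accession = df$Transcript_Accession,
    exon_serial = int_or_na(df$Exon_Serial),
    start = int_or_na(df$Exon_Start),
    end = int_or_na(df$Exon_End),
    stringsAsFactors = FALSE
  )
  set <- annotation_set(
    genes, transcripts, exons,
    provenance = list(source_format = "gene_table_tsv", source_path = path,
                      import_timestamp = format(Sys.time(), tz = "UTC"))
  )
  if (check) {
    rebuilt <- gene_table_export_df(build_gene_table(set))
    got <- df[GENE_TABLE_TSV_COLS]
    want <- as.data.frame(lapply(rebuilt[GENE_TABLE_TSV_COLS], cell),
                          stringsAsFactors = FALSE, check.names = FALSE)
    # compare in the canonical row order the writer uses
    key <- function(d) order(d$GeneID, d$Transcript_Accession,
                             as.integer(d$Exon_Serial))
    got <- got[key(got), , drop = FALSE]
    want <- want[key(want), , drop = FALSE]
    rownames(got) <- rownames(want) <- NULL
    for (cl in GENE_TABLE_TSV_COLS) {
      neq <- got[[cl]] != want[[cl]]
      if (any(neq)) {
        stop(sprintf(
          "integrity error: column %s at data row %d does not match re-derivation (file '%s', re-derived '%s')",
          cl, which(neq)[1L], got[[cl]][which(neq)[1L]],
          want[[cl]][which(neq)[1L]]
        ), call. = FALSE)
      }
    }
  }
  sort_annotation_set(set)
}

#' Write all three export tables at once
#'
#' @param set An [annotation_set].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default none).
#' @return Named character vector of the three paths.
#' @export
write_three_tables <- function(set, dir, prefix = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genes = file.path(dir, paste0(prefix, "Genes.tsv")),
    transcripts = file.path(dir, paste0(prefix, "Transcripts.tsv")),
    gene_table = file.path(dir, paste0(prefix, "Gene_Table.tsv"))
  )
  write_genes_table(set, paths[["genes"]])
  write_transcripts_table(set, paths[["transcripts"]])
  write_gene_table(set, paths[["gene_table"]])
  paths
}
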