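# Reading standard annotation formats (GFF3, GTF via rtracklayer) into an
# annotation_set, writing them back out, and the package's three-table TSV
# dialect (genes / transcripts / gene feature table). Coordinates are 1-based
# inclusive in every format handled here.

# Default attribute keys carrying curation metadata; GFF dialects differ, so
# they are overridable on every reader. Absent status keys yield NA, which
# the curation filter rejects (conservative).
default_attr_keys <- function() {
  list(
    gene_status = "gene_refseq_status",
    tx_status = "transcript_refseq_status",
    biotype = "gene_biotype",
    current = "in_current_annotation",
    live = "live_status",
    chromosome = "chromosome",
    protein = "protein_id"
  )
}

normalize_gene_type <- function(x) {
  x <- as.character(x)
  ifelse(!is.na(x) & x %in% c("protein_coding", "protein-coding"),
         "protein-coding", "other")
}

attr_or_na <- function(df, key) {
  if (!is.null(key) && key %in% names(df)) as.character(df[[key]])
  else rep(NA_character_, nrow(df))
}

as_flag <- function(x, default = TRUE) {
  out <- rep(default, length(x))
  known <- !is.na(x)
  out[known] <- tolower(x[known]) %in% c("true", "1", "yes", "current", "live")
  out
}

# Shared assembly: given per-feature data.frames extracted from a parsed
# file, build and validate the annotation_set. Transcription order is
# reconstructed from coordinates and strand (+: ascending starts,
# -: descending).
assemble_annotation_set <- function(genes_df, tx_df, exons_df, cds_df,
                                    provenance, strict = TRUE) {
  drop_tx <- character()
  complain <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    if (strict) stop(msg, call. = FALSE)
    warning(paste0(msg, " [skipped]"), call. = FALSE)
  }
  # orphan transcripts
  orphan <- !(tx_df$gene_key %in% genes_df$gene_key)
  if (any(orphan)) {
    complain("orphan Parent reference: transcript(s) %s point to no gene record",
             paste(head(tx_df$accession[orphan], 3L), collapse = ", "))
    tx_df <- tx_df[!orphan, , drop = FALSE]
  }
  # orphan exons / CDS parts
  for (nm in c("exons", "cds")) {
    df <- if (nm == "exons") exons_df else cds_df
    orphan <- !(df$tx_key %in% tx_df$tx_key)
    if (any(orphan)) {
      complain("orphan Parent reference: %s feature(s) %s point to no transcript",
               nm, paste(head(unique(df$tx_key[orphan]), 3L), collapse = ", "))
      df <- df[!orphan, , drop = FALSE]
    }
    if (nm == "exons") exons_df <- df else cds_df <- df
  }
  no_ex <- setdiff(tx_df$tx_key, exons_df$tx_key)
  if (length(no_ex)) {
    complain("transcript(s) without exons: %s",
             paste(head(no_ex, 3L), collapse = ", "))
    drop_tx <- c(drop_tx, no_ex)
  }
  # exons outside their transcript's recorded span
  if (nrow(tx_df) && !all(is.na(tx_df$tx_start))) {
    ti <- match(exons_df$tx_key, tx_df$tx_key)
    bad <- !is.na(tx_df$tx_start[ti]) &
      (exons_df$start < tx_df$tx_start[ti] | exons_df$end > tx_df$tx_end[ti])
    if (any(bad)) {
      offenders <- unique(exons_df$tx_key[bad])
      complain("exon outside its mRNA span in transcript(s): %s",
               paste(head(offenders, 3L), collapse = ", "))
      drop_tx <- c(drop_tx, offenders)
    }
  }
  tx_df <- tx_df[!(tx_df$tx_key %in% drop_tx), , drop = FALSE]
  exons_df <- exons_df[exons_df$tx_key %in% tx_df$tx_key, , drop = FALSE]
  cds_df <- cds_df[cds_df$tx_key %in% tx_df$tx_key, , drop = FALSE]

  gi <- match(tx_df$gene_key, genes_df$gene_key)
  tx_strand <- genes_df$strand[gi]

  # transcription order and serials
  ord <- order(exons_df$tx_key, exons_df$start)
  exons_df <- exons_df[ord, , drop = FALSE]
  serial <- stats::ave(exons_df$start, exons_df$tx_key,
                       FUN = seq_along)
  minus <- exons_df$tx_key %in% tx_df$tx_key[tx_strand == "-"]
  n_per <- stats::ave(exons_df$start, exons_df$tx_key, FUN = length)
  serial[minus] <- n_per[minus] - serial[minus] + 1L
  exons_df$exon_serial <- as.integer(serial)

  # merge CDS parts (plus any stop_codon parts already included in cds_df)
  cds_span <- if (nrow(cds_df)) {
    lo <- tapply(cds_df$start, cds_df$tx_key, min)
    hi <- tapply(cds_df$end, cds_df$tx_key, max)
    data.frame(tx_key = names(lo), cds_start = as.integer(lo),
               cds_end = as.integer(hi), stringsAsFactors = FALSE)
  } else {
    data.frame(tx_key = character(), cds_start = integer(),
               cds_end = integer(), stringsAsFactors = FALSE)
  }
  ci <- match(tx_df$tx_key, cds_span$tx_key)

  genes <- data.frame(
    gene_id = genes_df$gene_id,
    symbol = genes_df$symbol,
    chromosome = genes_df$chromosome,
    chrom_accession = genes_df$chrom_accession,
    strand = genes_df$strand,
    gene_start = genes_df$start,
    gene_end = genes_df$end,
    gene_type = genes_df$gene_type,
    gene_refseq_status = genes_df$gene_refseq_status,
    in_current_annotation = genes_df$in_current_annotation,
    live_status = genes_df$live_status,
    stringsAsFactors = FALSE
  )
  transcripts <- data.frame(
    gene_id = genes_df$gene_id[gi],
    accession = tx_df$accession,
    transcript_refseq_status = tx_df$status,
    protein_accession = tx_df$protein_accession,
    cds_start = cds_span$cds_start[ci],
    cds_end = cds_span$cds_end[ci],
    stringsAsFactors = FALSE
  )
  ei <- match(exons_df$tx_key, tx_df$tx_key)
  exons <- data.frame(
    gene_id = genes_df$gene_id[gi][ei],
    accession = tx_df$accession[ei],
    exon_serial = exons_df$exon_serial,
    start = exons_df$start,
    end = exons_df$end,
    stringsAsFactors = FALSE
  )
  # drop gene records with no surviving transcript only in lenient mode
  if (!strict) {
    keep <- genes$gene_id %in% transcripts$gene_id
    genes <- genes[keep | !(genes$gene_id %in% genes$gene_id[!keep]), ,
                   drop = FALSE]
  }
  set <- sort_annotation_set(annotation_set(
    genes, transcripts, exons, provenance = provenance, validate = FALSE
  ))
  validate_annotation_set(set)
  set
}

#' Read gene models from GFF3
#'
#' Expects the gene -> mRNA -> exon/CDS hierarchy with `ID`/`Parent` links.
#' Exons are sorted into transcription order and numbered; CDS parts are
#' merged into one genomic span per transcript. The CDS is assumed to
#' include the stop codon (set `stop_codon_included = FALSE` for dialects
#' that exclude it; the span is then extended by 3 mRNA bases across exon
#' junctions).
#'
#' @param path Path to a GFF3 file.
#' @param strict Fail on the first malformed record (default); otherwise
#'   skip offending records with a warning.
#' @param attr_keys Named list of attribute keys carrying gene/transcript
#'   RefSeq status, biotype, currency, liveness, chromosome name and protein
#'   accession; see `genefeatr:::default_attr_keys()` for defaults. Absent
#'   status attributes become `NA` (rejected by the default curation
#'   policy); absent currency/liveness default to current/live.
#' @param stop_codon_included Is the GFF3 CDS span stop-inclusive? Default
#'   `TRUE`.
#' @return An [annotation_set].
#' @export
read_gff3 <- function(path, strict = TRUE, attr_keys = default_attr_keys(),
                      stop_codon_included = TRUE) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  # Parent is a CharacterList; flatten (taking the first parent; multi-parent
  # exons are duplicated per parent below)
  parents <- df$Parent
  df$n_parents <- lengths(parents)
  first_parent <- rep(NA_character_, nrow(df))
  first_parent[df$n_parents > 0L] <- vapply(
    parents[df$n_parents > 0L], `[[`, "", 1L
  )
  df$parent1 <- first_parent

  gdf <- df[df$type == "gene", , drop = FALSE]
  genes_df <- data.frame(
    gene_key = as.character(gdf$ID),
    gene_id = if ("gene_id" %in% names(gdf) && !anyNA(gdf$gene_id))
      as.character(gdf$gene_id) else as.character(gdf$ID),
    symbol = if ("Name" %in% names(gdf)) as.character(gdf$Name)
      else as.character(gdf$ID),
    chromosome = {
      chr <- attr_or_na(gdf, attr_keys$chromosome)
      ifelse(is.na(chr), chromosome_from_accession(gdf$seqnames), chr)
    },
    chrom_accession = gdf$seqnames,
    strand = gdf$strand,
    start = as.integer(gdf$start),
    end = as.integer(gdf$end),
    gene_type = normalize_gene_type(attr_or_na(gdf, attr_keys$biotype)),
    gene_refseq_status = attr_or_na(gdf, attr_keys$gene_status),
    in_current_annotation = as_flag(attr_or_na(gdf, attr_keys$current)),
    live_status = as_flag(attr_or_na(gdf, attr_keys$live)),
    stringsAsFactors = FALSE
  )
  tdf <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_df <- data.frame(
    tx_key = as.character(tdf$ID),
    gene_key = tdf$parent1,
    accession = if ("transcript_id" %in% names(tdf))
      ifelse(is.na(tdf$transcript_id), as.character(tdf$ID),
             as.character(tdf$transcript_id))
      else as.character(tdf$ID),
    status = attr_or_na(tdf, attr_keys$tx_status),
    protein_accession = attr_or_na(tdf, attr_keys$protein),
    tx_start = as.integer(tdf$start),
    tx_end = as.integer(tdf$end),
    stringsAsFactors = FALSE
  )
  expand_parts <- function(part) {
    pdf <- df[df$type == part, , drop = FALSE]
    reps <- pmax(pdf$n_parents, 1L)
    keys <- character(sum(reps))
    k <- 1L
    for (i in seq_len(nrow(pdf))) {
      p <- parents[df$type == part][[i]]
      if (!length(p)) p <- NA_character_
      keys[k:(k + length(p) - 1L)] <- p
      k <- k + length(p)
    }
    data.frame(
      tx_key = keys,
      start = rep(as.integer(pdf$start), reps),
      end = rep(as.integer(pdf$end), reps),
      stringsAsFactors = FALSE
    )
  }
  exons_df <- expand_parts("exon")
  cds_df <- expand_parts("CDS")
  set <- assemble_annotation_set(
    genes_df, tx_df, exons_df, cds_df,
    provenance = list(source_format = "gff3", source_path = path,
                      import_timestamp = format(Sys.time(), tz = "UTC")),
    strict = strict
  )
  if (!stop_codon_included) set <- extend_cds_spans(set, 3L)
  set
}

#' Read gene models from GTF (2.2)
#'
#' Requires `gene_id`/`transcript_id` attributes. Separate `stop_codon`
#' features, when present, are merged into the transcript's CDS span so
#' that the stored span always includes the stop codon.
#'
#' @inheritParams read_gff3
#' @return An [annotation_set].
#' @export
read_gtf <- function(path, strict = TRUE, attr_keys = default_attr_keys()) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  if (!all(c("gene_id", "transcript_id") %in% names(df))) {
    stop("GTF lacks gene_id/transcript_id attributes", call. = FALSE)
  }
  gdf <- df[df$type == "gene", , drop = FALSE]
  if (!nrow(gdf)) {
    stop("GTF lacks gene features; cannot recover gene-level metadata",
         call. = FALSE)
  }
  genes_df <- data.frame(
    gene_key = as.character(gdf$gene_id),
    gene_id = as.character(gdf$gene_id),
    symbol = if ("gene_name" %in% names(gdf))
      ifelse(is.na(gdf$gene_name), as.character(gdf$gene_id),
             as.character(gdf$gene_name))
      else as.character(gdf$gene_id),
    chromosome = {
      chr <- attr_or_na(gdf, attr_keys$chromosome)
      ifelse(is.na(chr), chromosome_from_accession(gdf$seqnames), chr)
    },
    chrom_accession = gdf$seqnames,
    strand = gdf$strand,
    start = as.integer(gdf$start),
    end = as.integer(gdf$end),
    gene_type = normalize_gene_type(attr_or_na(gdf, attr_keys$biotype)),
    gene_refseq_status = attr_or_na(gdf, attr_keys$gene_status),
    in_current_annotation = as_flag(attr_or_na(gdf, attr_keys$current)),
    live_status = as_flag(attr_or_na(gdf, attr_keys$live)),
    stringsAsFactors = FALSE
  )
  tdf <- df[df$type == "transcript", , drop = FALSE]
  tx_df <- data.frame(
    tx_key = as.character(tdf$transcript_id),
    gene_key = as.character(tdf$gene_id),
    accession = as.character(tdf$transcript_id),
    status = attr_or_na(tdf, attr_keys$tx_status),
    protein_accession = attr_or_na(tdf, attr_keys$protein),
    tx_start = as.integer(tdf$start),
    tx_end = as.integer(tdf$end),
    stringsAsFactors = FALSE
  )
  part_df <- function(types) {
    pdf <- df[df$type %in% types, , drop = FALSE]
    data.frame(
      tx_key = as.character(pdf$transcript_id),
      start = as.integer(pdf$start),
      end = as.integer(pdf$end),
      stringsAsFactors = FALSE
    )
  }
  assemble_annotation_set(
    genes_df, tx_df,
    exons_df = part_df("exon"),
    cds_df = part_df(c("CDS", "stop_codon")),
    provenance = list(source_format = "gtf", source_path = path,
                      import_timestamp = format(Sys.time(), tz = "UTC")),
    strict = strict
  )
}

# Extend every CDS span 3 mRNA bases in the 3' direction (stop codon), moving
# across exon junctions where necessary.
extend_cds_spans <- function(set, by = 3L) {
  recs <- set_transcript_records(set)
  for (i in seq_len(nrow(set$transcripts))) {
    t <- recs[[set$transcripts$accession[i]]]
    if (is.na(t$cds_start)) next
    sp <- split_utrs(t)
    new_hi <- sp$utr5_len + sp$cds_len + by
    if (new_hi > sp$transcript_len) {
      stop(sprintf("transcript %s: cannot extend CDS past transcript end",
                   t$accession), call. = FALSE)
    }
    g <- mrna_pos_to_genomic(t, new_hi)
    if (t$strand == "+") {
      set$transcripts$cds_end[i] <- g
    } else {
      set$transcripts$cds_start[i] <- g
    }
  }
  validate_annotation_set(set)
  set
}

# ---- chromosome accession map --------------------------------------------

# Human RefSeq chromosome accessions (GRCh38 versions); used by the
# synthetic generator and to recover chromosome names from accessions.
human_chrom_accessions <- function() {
  acc <- c(sprintf("NC_%06d.%d", 1:22,
                   c(11, 12, 12, 12, 10, 12, 14, 11, 12, 11,
                     10, 12, 11, 9, 10, 10, 11, 10, 10, 11, 9, 11)),
           "NC_000023.11", "NC_000024.10", "NC_012920.1")
  stats::setNames(acc, c(as.character(1:22), "X", "Y", "MT"))
}

chromosome_from_accession <- function(acc) {
  map <- human_chrom_accessions()
  nm <- names(map)[match(acc, map)]
  ifelse(is.na(nm), as.character(acc), nm)
}

# ---- GFF3 / GTF writers ---------------------------------------------------

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write an annotation set as GFF3
#'
#' Emits gene/mRNA/exon/CDS features with `ID`/`Parent` links and the
#' curation metadata attributes the readers understand. CDS features are
#' stop-codon inclusive (one CDS part per coding exon portion).
#'
#' @param set An [annotation_set].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(set, path) {
  set <- sort_annotation_set(set)
  recs <- set_transcript_records(set)
  g <- set$genes
  lines <- c("##gff-version 3")
  fmt <- function(seqid, type, start, end, strand, attrs) {
    sprintf("%s\tgenefeatr\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, type, start, end, strand, attrs)
  }
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    lines <- c(lines, fmt(
      g$chrom_accession[i], "gene", g$gene_start[i], g$gene_end[i],
      g$strand[i],
      sprintf(paste0(
        "ID=gene-%s;gene_id=%s;Name=%s;gene_biotype=%s;",
        "gene_refseq_status=%s;in_current_annotation=%s;live_status=%s;",
        "chromosome=%s"),
        gff_escape(gid), gff_escape(gid), gff_escape(g$symbol[i]),
        ifelse(g$gene_type[i] == "protein-coding", "protein_coding", "other"),
        g$gene_refseq_status[i],
        tolower(as.character(g$in_current_annotation[i])),
        tolower(as.character(g$live_status[i])),
        gff_escape(g$chromosome[i]))
    ))
    tx <- set$transcripts[set$transcripts$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(tx))) {
      t <- recs[[tx$accession[j]]]
      lo <- min(t$exon_starts); hi <- max(t$exon_ends)
      tid <- sprintf("rna-%s", tx$accession[j])
      prot <- tx$protein_accession[j]
      lines <- c(lines, fmt(
        g$chrom_accession[i], "mRNA", lo, hi, g$strand[i],
        sprintf(paste0("ID=%s;Parent=gene-%s;transcript_id=%s;",
                       "transcript_refseq_status=%s%s"),
                tid, gff_escape(gid), gff_escape(tx$accession[j]),
                tx$transcript_refseq_status[j],
                if (is.na(prot)) "" else sprintf(";protein_id=%s", prot))
      ))
      # exon rows in genomic order (readers reconstruct transcription order)
      ord <- order(t$exon_starts)
      lines <- c(lines, fmt(
        g$chrom_accession[i], "exon",
        t$exon_starts[ord], t$exon_ends[ord], g$strand[i],
        sprintf("Parent=%s", tid)
      ))
      if (!is.na(t$cds_start)) {
        ce <- derive_coding_exons(t)
        ord <- order(ce$start)
        lines <- c(lines, fmt(
          g$chrom_accession[i], "CDS", ce$start[ord], ce$end[ord],
          g$strand[i], sprintf("Parent=%s", tid)
        ))
      }
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

gtf_attrs <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(v) is.na(v) || is.null(v), TRUE)]
  paste(sprintf('%s "%s";', names(kv), unlist(kv)), collapse = " ")
}

#' Write an annotation set as GTF (2.2)
#'
#' Emits gene/transcript/exon/CDS features; the stop codon is written as a
#' separate `stop_codon` feature (split across exon junctions when the last
#' 3 coding bases straddle one) and excluded from the CDS features, matching
#' common GTF practice. [read_gtf()] merges it back.
#'
#' @inheritParams write_gff3
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(set, path) {
  set <- sort_annotation_set(set)
  recs <- set_transcript_records(set)
  g <- set$genes
  lines <- character()
  fmt <- function(seqid, type, start, end, strand, attrs) {
    sprintf("%s\tgenefeatr\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, type, start, end, strand, attrs)
  }
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    gattr <- gtf_attrs(
      gene_id = gid, gene_name = g$symbol[i],
      gene_biotype = ifelse(g$gene_type[i] == "protein-coding",
                            "protein_coding", "other"),
      gene_refseq_status = g$gene_refseq_status[i],
      in_current_annotation = tolower(as.character(g$in_current_annotation[i])),
      live_status = tolower(as.character(g$live_status[i])),
      chromosome = g$chromosome[i]
    )
    lines <- c(lines, fmt(g$chrom_accession[i], "gene",
                          g$gene_start[i], g$gene_end[i], g$strand[i], gattr))
    tx <- set$transcripts[set$transcripts$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(tx))) {
      t <- recs[[tx$accession[j]]]
      base_attr <- gtf_attrs(
        gene_id = gid, transcript_id = tx$accession[j],
        transcript_refseq_status = tx$transcript_refseq_status[j],
        protein_id = tx$protein_accession[j]
      )
      lo <- min(t$exon_starts); hi <- max(t$exon_ends)
      lines <- c(lines, fmt(g$chrom_accession[i], "transcript",
                            lo, hi, g$strand[i], base_attr))
      ord <- order(t$exon_starts)
      lines <- c(lines, fmt(g$chrom_accession[i], "exon",
                            t$exon_starts[ord], t$exon_ends[ord],
                            g$strand[i], base_attr))
      if (!is.na(t$cds_start)) {
        sp <- split_utrs(t)
        m_lo <- sp$utr5_len + 1L
        m_hi <- sp$utr5_len + sp$cds_len
        if (sp$cds_len > 3L) {
          cds_seg <- mrna_range_to_segments(t, m_lo, m_hi - 3L)
          stop_seg <- mrna_range_to_segments(t, m_hi - 2L, m_hi)
        } else {
          cds_seg <- mrna_range_to_segments(t, m_lo, m_hi)
          stop_seg <- NULL
        }
        ord <- order(cds_seg$start)
        lines <- c(lines, fmt(g$chrom_accession[i], "CDS",
                              cds_seg$start[ord], cds_seg$end[ord],
                              g$strand[i], base_attr))
        if (!is.null(stop_seg)) {
          ord <- order(stop_seg$start)
          lines <- c(lines, fmt(g$chrom_accession[i], "stop_codon",
                                stop_seg$start[ord], stop_seg$end[ord],
                                g$strand[i], base_attr))
        }
      }
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
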