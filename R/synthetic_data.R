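# Seeded synthetic annotation sets with exact ground truth. The generator
# emulates the structure the analysis assumes -- multi-isoform protein-coding
# gene models with shared exons, mono-exonic genes, both strands, 5'
# UTR/CDS/3' UTR structure with the stop codon inside the CDS, a mix of
# RefSeq statuses, and contaminants (pseudogenes, mitochondrial, non-current
# and XM_-only records) that exercise every curation rule -- and counts every
# expected statistic as it emits, so pipeline recovery can be checked
# cell-for-cell without external downloads.

#' Parameters for the synthetic annotation generator
#'
#' Defaults target the length and count medians typical of the curated
#' human nuclear protein-coding set (exon median ~131 bp, intron median
#' ~1,747 bp, ~9 exons per transcript, ~2.6 isoforms per gene, ~5.5%
#' mono-exonic genes). Length distributions are log-normal and count
#' distributions Poisson/geometric: pragmatic families chosen to hit those
#' medians, not claims about biology. Intron lengths are floored at 30 bp
#' (canonically spliced human introns are never shorter).
#'
#' @param n_genes Number of genes to generate.
#' @param mean_isoforms Mean transcripts per gene (geometric, support >= 1).
#' @param max_isoforms Cap on isoforms per gene.
#' @param exon_count_lambda Poisson rate; multi-exonic templates have
#'   `2 + rpois(lambda)` exons.
#' @param mono_exonic_fraction Fraction of genes whose template (and hence
#'   all isoforms) is a single exon.
#' @param exon_len_meanlog,exon_len_sdlog Log-normal exon length (bp).
#' @param min_exon_len Floor on exon length (bp).
#' @param mono_exon_len_min Floor on mono-exonic gene exon length (bp).
#' @param intron_len_meanlog,intron_len_sdlog Log-normal intron length (bp).
#' @param min_intron_len Floor on intron length (bp, default 30).
#' @param utr5_meanlog,utr5_sdlog,utr3_meanlog,utr3_sdlog Log-normal UTR
#'   lengths (bp, capped so the CDS keeps >= 3 bp).
#' @param shared_exon_fraction Probability that a secondary isoform reuses
#'   its sibling's terminal-exon coordinates unchanged (internal exons are
#'   always shared when not skipped).
#' @param exon_skip_prob Per-internal-exon skipping probability in
#'   secondary isoforms.
#' @param minus_strand_fraction Fraction of genes on the minus strand.
#' @param gene_status_probs,tx_status_probs Named probabilities over
#'   REVIEWED/VALIDATED for clean records.
#' @param extra_model_tx_prob Probability that a secondary isoform of a
#'   clean gene is an XM_/MODEL prediction (removed at transcript level).
#' @param contaminant_fractions Named probabilities for whole-gene defects:
#'   `pseudogene`, `model_status`, `non_current`, `chrMT`, `xm_only`.
#' @param seed Integer seed driving one explicit RNG stream.
#' @return Object of class `generator_params`.
#' @export
generator_params <- function(n_genes = 200L,
                             mean_isoforms = 2.6,
                             max_isoforms = 12L,
                             exon_count_lambda = 7.5,
                             mono_exonic_fraction = 0.055,
                             exon_len_meanlog = log(131),
                             exon_len_sdlog = 1.31,
                             min_exon_len = 2L,
                             mono_exon_len_min = 60L,
                             intron_len_meanlog = log(1747),
                             intron_len_sdlog = 1.66,
                             min_intron_len = 30L,
                             utr5_meanlog = log(170), utr5_sdlog = 0.8,
                             utr3_meanlog = log(800), utr3_sdlog = 1.0,
                             shared_exon_fraction = 0.7,
                             exon_skip_prob = 0.15,
                             minus_strand_fraction = 0.5,
                             gene_status_probs = c(REVIEWED = 0.35, VALIDATED = 0.65),
                             tx_status_probs = c(REVIEWED = 0.3, VALIDATED = 0.7),
                             extra_model_tx_prob = 0.08,
                             contaminant_fractions = c(pseudogene = 0.10,
                                                       model_status = 0.05,
                                                       non_current = 0.03,
                                                       chrMT = 0.02,
                                                       xm_only = 0.03),
                             seed = 1L) {
  p <- as.list(environment())
  probs <- c(p$mono_exonic_fraction, p$shared_exon_fraction, p$exon_skip_prob,
             p$minus_strand_fraction, p$extra_model_tx_prob,
             p$contaminant_fractions)
  if (any(probs < 0 | probs > 1)) {
    stop("parameter conflict: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (sum(p$contaminant_fractions) >= 1) {
    stop("parameter conflict: contaminant fractions sum to >= 1", call. = FALSE)
  }
  if (p$mean_isoforms < 1 || p$max_isoforms < 1L) {
    stop("parameter conflict: need at least one isoform per gene", call. = FALSE)
  }
  if (p$n_genes < 1L) {
    stop("parameter conflict: n_genes must be >= 1", call. = FALSE)
  }
  structure(p, class = "generator_params")
}

with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  code
}

# ground-truth summary of a numeric vector (computed independently of
# summarize_values; same spreadsheet definitions)
gt_ss <- function(v) {
  n <- length(v)
  if (n == 0L) {
    return(list(n = 0L, median = NA_real_, mean = NA_real_, sd = NA_real_,
                min = NA_real_, max = NA_real_, total = NA_real_))
  }
  list(n = n, median = stats::median(v), mean = sum(v) / n,
       sd = if (n > 1L) stats::sd(v) else NA_real_,
       min = min(v), max = max(v), total = sum(v))
}

# representative mask for ground-truth non-redundancy: rows assumed ordered
# by (gene_id, accession, serial); TRUE marks the first row of each
# (chrom_accession, strand, start, end) group.
gt_nr_first <- function(rows) {
  ord <- order(rows$gene_id, rows$accession, rows$serial)
  key <- paste(rows$chrom_accession, rows$strand, rows$start, rows$end,
               sep = "\r")
  first <- logical(nrow(rows))
  first[ord] <- !duplicated(key[ord])
  first
}

#' Generate a synthetic annotation set with exact ground truth
#'
#' Deterministic for a fixed seed. The ground truth is counted as the
#' models are emitted -- feature coordinates, lengths, last-exon flags and
#' non-redundancy collapse are tracked by the generator itself, not
#' re-derived through the pipeline -- so a full pipeline run
#' ([apply_curation()] + [build_report()]) can be compared against it
#' cell-for-cell.
#'
#' @param params A [generator_params] object.
#' @return List with `set` (the [annotation_set], contaminants included)
#'   and `truth` (class `ground_truth`: `report`, a [build_report()]-shaped
#'   list of expected cells for the curated subset; `filter`, the expected
#'   [apply_curation()] accounting; and `contaminants`, the defect counts).
#' @export
generate_annotation <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  with_rng_seed(params$seed, generate_annotation_impl(params))
}

generate_annotation_impl <- function(p) {
  chrom_names <- c(as.character(1:22), "X", "Y")
  chrom_w <- c(22:1, 8, 2)
  acc_map <- human_chrom_accessions()
  defects <- c("pseudogene", "model_status", "non_current", "chrMT", "xm_only")
  defect_probs <- c(1 - sum(p$contaminant_fractions),
                    p$contaminant_fractions[defects])

  genes <- list(); txs <- list(); exs <- list()
  # ground-truth accumulators (curated subset only)
  tr_exon <- list(); tr_cod <- list(); tr_intr <- list(); tr_tx <- list()
  tr_gene <- list()
  defect_count <- stats::setNames(integer(length(defects)), defects)
  removed_tx_in_kept <- 0L
  acc_counter <- 0L

  for (i in seq_len(p$n_genes)) {
    gene_id <- as.character(100000L + i)
    symbol <- sprintf("GENE%04d", i)
    defect <- sample(c("clean", defects), 1L, prob = defect_probs)
    if (defect != "clean") defect_count[defect] <- defect_count[defect] + 1L
    chrom <- if (defect == "chrMT") "MT" else
      sample(chrom_names, 1L, prob = chrom_w)
    chrom_acc <- unname(acc_map[chrom])
    strand <- if (stats::runif(1) < p$minus_strand_fraction) "-" else "+"
    gene_type <- if (defect == "pseudogene") "other" else "protein-coding"
    gene_status <- if (defect == "model_status") "MODEL" else
      sample(names(p$gene_status_probs), 1L, prob = p$gene_status_probs)
    in_current <- defect != "non_current"

    mono <- stats::runif(1) < p$mono_exonic_fraction
    n_template <- if (mono) 1L else 2L + stats::rpois(1L, p$exon_count_lambda)
    ex_len <- pmax(p$min_exon_len,
                   as.integer(round(stats::rlnorm(n_template,
                                                  p$exon_len_meanlog,
                                                  p$exon_len_sdlog))))
    if (mono) ex_len <- pmax(ex_len, p$mono_exon_len_min)
    gaps <- if (n_template > 1L) {
      pmax(p$min_intron_len,
           as.integer(round(stats::rlnorm(n_template - 1L,
                                          p$intron_len_meanlog,
                                          p$intron_len_sdlog))))
    } else integer()
    gstart <- sample.int(150000000L, 1L) + 100000L
    tstarts <- integer(n_template); tends <- integer(n_template)
    pos <- gstart
    for (k in seq_len(n_template)) {
      tstarts[k] <- pos
      tends[k] <- pos + ex_len[k] - 1L
      pos <- tends[k] + (if (k < n_template) gaps[k] else 0L) + 1L
    }

    n_iso <- 1L + min(stats::rgeom(1L, 1 / p$mean_isoforms),
                      p$max_isoforms - 1L)
    gene_lo <- NA_integer_; gene_hi <- NA_integer_
    gene_retained <- defect == "clean"
    iso_rows <- list()
    for (j in seq_len(n_iso)) {
      keep <- rep(TRUE, n_template)
      if (j > 1L && n_template > 2L) {
        keep[2:(n_template - 1L)] <-
          stats::runif(n_template - 2L) >= p$exon_skip_prob
      }
      starts <- tstarts[keep]; ends <- tends[keep]
      if (j > 1L && stats::runif(1) < 1 - p$shared_exon_fraction) {
        # alternative transcription-start boundary: shrink the 5' terminal
        # exon inward (keeps exon order and gaps intact)
        if (strand == "+") {
          len1 <- ends[1L] - starts[1L] + 1L
          if (len1 > p$min_exon_len) {
            starts[1L] <- starts[1L] + sample.int(len1 - p$min_exon_len, 1L)
          }
        } else {
          k <- length(ends)
          lenk <- ends[k] - starts[k] + 1L
          if (lenk > p$min_exon_len) {
            ends[k] <- ends[k] - sample.int(lenk - p$min_exon_len, 1L)
          }
        }
      }
      # transcription order
      ord <- if (strand == "+") order(starts) else order(-starts)
      t_starts <- starts[ord]; t_ends <- ends[ord]
      n_ex <- length(t_starts)
      exlens <- t_ends - t_starts + 1L
      L <- sum(exlens)
      u5 <- as.integer(round(stats::rlnorm(1L, p$utr5_meanlog, p$utr5_sdlog)))
      u3 <- as.integer(round(stats::rlnorm(1L, p$utr3_meanlog, p$utr3_sdlog)))
      if (L < 10L) { u5 <- 0L; u3 <- 0L }
      u5 <- min(u5, max(0L, (L - 3L) %/% 2L))
      u3 <- min(u3, L - 3L - u5)
      if (u3 < 0L) u3 <- 0L
      cds <- L - u5 - u3
      r3 <- cds %% 3L
      if (cds - r3 >= 3L) { cds <- cds - r3; u3 <- u3 + r3 }
      trec <- list(accession = "tmp", strand = strand,
                   exon_starts = t_starts, exon_ends = t_ends)
      gpos1 <- mrna_pos_to_genomic(trec, u5 + 1L)
      gpos2 <- mrna_pos_to_genomic(trec, u5 + cds)
      cds_start <- min(gpos1, gpos2); cds_end <- max(gpos1, gpos2)

      is_xm <- defect == "xm_only" ||
        (j > 1L && stats::runif(1) < p$extra_model_tx_prob)
      acc_counter <- acc_counter + 1L
      accession <- sprintf("%s_%06d.1", if (is_xm) "XM" else "NM", acc_counter)
      protein <- sprintf("%s_%06d.1", if (is_xm) "XP" else "NP", acc_counter)
      tx_status <- if (is_xm && defect != "xm_only") "MODEL" else
        sample(names(p$tx_status_probs), 1L, prob = p$tx_status_probs)

      gene_lo <- min(gene_lo, t_starts, na.rm = TRUE)
      gene_hi <- max(gene_hi, t_ends, na.rm = TRUE)
      iso_rows[[j]] <- list(accession = accession, status = tx_status,
                            protein = protein,
                            starts = t_starts, ends = t_ends,
                            cds_start = cds_start, cds_end = cds_end)
      txs[[length(txs) + 1L]] <- data.frame(
        gene_id = gene_id, accession = accession,
        transcript_refseq_status = tx_status, protein_accession = protein,
        cds_start = cds_start, cds_end = cds_end, stringsAsFactors = FALSE
      )
      exs[[length(exs) + 1L]] <- data.frame(
        gene_id = gene_id, accession = accession,
        exon_serial = seq_len(n_ex), start = t_starts, end = t_ends,
        stringsAsFactors = FALSE
      )

      tx_retained <- gene_retained && !is_xm &&
        tx_status %in% c("REVIEWED", "VALIDATED")
      if (gene_retained && !tx_retained) {
        removed_tx_in_kept <- removed_tx_in_kept + 1L
      }
      if (tx_retained) {
        is_last <- seq_len(n_ex) == n_ex
        tr_exon[[length(tr_exon) + 1L]] <- data.frame(
          gene_id = gene_id, symbol = symbol, accession = accession,
          chrom_accession = chrom_acc, strand = strand,
          serial = seq_len(n_ex), start = t_starts, end = t_ends,
          len = exlens, is_last = is_last, stringsAsFactors = FALSE
        )
        clo <- pmax(t_starts, cds_start); chi <- pmin(t_ends, cds_end)
        ck <- clo <= chi
        if (any(ck)) {
          cser <- cumsum(ck)[ck]
          tr_cod[[length(tr_cod) + 1L]] <- data.frame(
            gene_id = gene_id, symbol = symbol, accession = accession,
            chrom_accession = chrom_acc, strand = strand,
            serial = cser, start = clo[ck], end = chi[ck],
            len = chi[ck] - clo[ck] + 1L,
            is_last = cser == max(cser), stringsAsFactors = FALSE
          )
        }
        if (n_ex > 1L) {
          if (strand == "+") {
            istart <- t_ends[-n_ex] + 1L
            iend <- t_starts[-1L] - 1L
          } else {
            istart <- t_ends[-1L] + 1L
            iend <- t_starts[-n_ex] - 1L
          }
          tr_intr[[length(tr_intr) + 1L]] <- data.frame(
            gene_id = gene_id, symbol = symbol, accession = accession,
            chrom_accession = chrom_acc, strand = strand,
            serial = seq_len(n_ex - 1L), start = istart, end = iend,
            len = iend - istart + 1L, stringsAsFactors = FALSE
          )
        }
        tr_tx[[length(tr_tx) + 1L]] <- data.frame(
          gene_id = gene_id, symbol = symbol, accession = accession,
          n_exons = n_ex, n_coding = sum(ck), n_introns = n_ex - 1L,
          len = L, u5 = u5, cds = cds, u3 = u3, stringsAsFactors = FALSE
        )
      }
    }
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gene_id, symbol = symbol, chromosome = chrom,
      chrom_accession = chrom_acc, strand = strand,
      gene_start = gene_lo, gene_end = gene_hi,
      gene_type = gene_type, gene_refseq_status = gene_status,
      in_current_annotation = in_current, live_status = TRUE,
      stringsAsFactors = FALSE
    )
    if (gene_retained) {
      tr_gene[[length(tr_gene) + 1L]] <- data.frame(
        gene_id = gene_id, symbol = symbol, chromosome = chrom,
        len = gene_hi - gene_lo + 1L, stringsAsFactors = FALSE
      )
    }
  }

  set <- sort_annotation_set(annotation_set(
    do.call(rbind, genes), do.call(rbind, txs), do.call(rbind, exs),
    provenance = list(source_format = "synthetic",
                      seed = p$seed, n_genes = p$n_genes)
  ))
  truth <- build_ground_truth(
    gene_rows = do.call(rbind, tr_gene),
    tx_rows = do.call(rbind, tr_tx),
    exon_rows = do.call(rbind, tr_exon),
    cod_rows = do.call(rbind, tr_cod),
    intr_rows = do.call(rbind, tr_intr),
    defect_count = defect_count,
    removed_tx_in_kept = removed_tx_in_kept,
    n_input_genes = p$n_genes,
    n_input_tx = length(txs)
  )
  list(set = set, truth = truth)
}

# assemble the ground-truth report (build_report shape, numeric cells only)
build_ground_truth <- function(gene_rows, tx_rows, exon_rows, cod_rows,
                               intr_rows, defect_count, removed_tx_in_kept,
                               n_input_genes, n_input_tx) {
  empty <- function(cols) {
    as.data.frame(setNames(rep(list(integer()), length(cols)), cols))
  }
  if (is.null(gene_rows)) gene_rows <- empty(c("gene_id", "len", "chromosome"))
  if (is.null(tx_rows)) {
    tx_rows <- empty(c("gene_id", "n_exons", "n_coding", "n_introns",
                       "len", "u5", "cds", "u3"))
  }
  for (nm in c("exon_rows", "cod_rows", "intr_rows")) {
    if (is.null(get(nm))) {
      assign(nm, empty(c("gene_id", "accession", "chrom_accession", "strand",
                         "serial", "start", "end", "len", "is_last")))
    }
  }
  canon <- c(as.character(1:22), "X", "Y", "MT")
  tab <- table(gene_rows$chromosome)
  keys <- c(intersect(canon, names(tab)), sort(setdiff(names(tab), canon)))
  per_chrom <- stats::setNames(as.integer(tab[keys]), keys)
  n_g <- nrow(gene_rows)

  pt_ss <- function(v, exclude_zero_min = FALSE) {
    if (!length(v) || (exclude_zero_min && all(v == 0L))) return(gt_ss(numeric(0)))
    s <- gt_ss(v)
    if (exclude_zero_min) s$min <- min(v[v > 0L])
    s
  }
  feat_block <- function(rows, with_not_last, with_pt, pt_values,
                         exclude_zero_min = FALSE) {
    first <- if (nrow(rows)) gt_nr_first(rows) else logical(0)
    blk <- list(
      raw = c(
        list(n = nrow(rows)),
        if (with_pt) list(per_transcript = pt_ss(pt_values, exclude_zero_min)),
        list(length = gt_ss(rows$len)),
        if (with_not_last) list(not_last = gt_ss(rows$len[!rows$is_last]))
      ),
      nonredundant = c(
        list(n = sum(first), length = gt_ss(rows$len[first])),
        if (with_not_last) {
          list(not_last = gt_ss(rows$len[first & !rows$is_last]))
        }
      )
    )
    blk
  }

  report <- list(
    genes = list(
      n = n_g,
      per_chromosome = per_chrom,
      min_count = if (n_g) min(per_chrom) else NULL,
      max_count = if (n_g) max(per_chrom) else NULL,
      mean_per_chromosome = if (n_g) floor(n_g / 24 + 0.5 + 1e-9) else NA_real_,
      length = gt_ss(gene_rows$len)
    ),
    mrnas = list(
      n = nrow(tx_rows),
      n_nm = nrow(tx_rows),
      length = gt_ss(tx_rows$len),
      utr5 = gt_ss(tx_rows$u5),
      cds = gt_ss(tx_rows$cds),
      utr3 = gt_ss(tx_rows$u3)
    ),
    exons = feat_block(exon_rows, TRUE, TRUE, tx_rows$n_exons),
    coding_exons = feat_block(cod_rows, TRUE, TRUE, tx_rows$n_coding),
    introns = feat_block(intr_rows, FALSE, TRUE,
                         tx_rows$n_introns, exclude_zero_min = TRUE)
  )
  structure(
    list(
      report = report,
      filter = list(
        n_input_genes = n_input_genes,
        n_input_transcripts = n_input_tx,
        removed_genes = c(
          gene_type = unname(defect_count[["pseudogene"]]),
          gene_refseq_status = unname(defect_count[["model_status"]]),
          not_current = unname(defect_count[["non_current"]]),
          chromosome = unname(defect_count[["chrMT"]]),
          no_qualifying_transcript = unname(defect_count[["xm_only"]])
        ),
        removed_transcripts_in_kept_genes = removed_tx_in_kept,
        n_retained_genes = n_g,
        n_retained_transcripts = nrow(tx_rows)
      ),
      contaminants = defect_count
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d curated genes, %d transcripts; contaminants: %s\n",
    x$filter$n_retained_genes, x$filter$n_retained_transcripts,
    paste(sprintf("%s=%d", names(x$contaminants), x$contaminants),
          collapse = ", ")
  ))
  invisible(x)
}

#' Hand-built boundary fixtures
#'
#' A small fixed annotation set exercising every boundary shape the
#' statistics must handle: a 2-bp exon (last exon of a 16-exon transcript),
#' a 1-bp coding exon (CDS starting on the last base of exon 1), a
#' minus-strand transcript whose intron 4 is exactly 26 bp (below the 30-bp
#' splicing floor, so flagged), a 30-bp intron (at the floor, not flagged),
#' a mono-exonic gene (single row, no intron) and a 363-exon transcript.
#' All values are hand-derivable from the coordinates.
#'
#' @return An [annotation_set] of 6 curated-passing genes.
#' @export
make_edge_fixtures <- function() {
  genes <- list(); txs <- list(); exs <- list()
  add_gene <- function(gene_id, symbol, chrom, strand, starts, ends,
                       cds_start, cds_end, accession, protein) {
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = gene_id, symbol = symbol, chromosome = chrom,
      chrom_accession = unname(human_chrom_accessions()[chrom]),
      strand = strand, gene_start = min(starts), gene_end = max(ends),
      gene_type = "protein-coding", gene_refseq_status = "REVIEWED",
      in_current_annotation = TRUE, live_status = TRUE,
      stringsAsFactors = FALSE
    )
    txs[[length(txs) + 1L]] <<- data.frame(
      gene_id = gene_id, accession = accession,
      transcript_refseq_status = "REVIEWED", protein_accession = protein,
      cds_start = cds_start, cds_end = cds_end, stringsAsFactors = FALSE
    )
    ord <- if (strand == "+") order(starts) else order(-starts)
    exs[[length(exs) + 1L]] <<- data.frame(
      gene_id = gene_id, accession = accession,
      exon_serial = seq_along(starts), start = starts[ord], end = ends[ord],
      stringsAsFactors = FALSE
    )
  }
  # 16 exons, E1..E15 100 bp, E16 2 bp; CDS ends inside E15
  s <- 10000L + (0:15) * 200L
  e <- s + 99L; e[16L] <- s[16L] + 1L
  add_gene("900001", "SHEX1", "5", "+", s, e, 10050L, 12850L,
           "NM_900001.1", "NP_900001.1")
  # CDS starts on the last base of E1 -> 1-bp coding portion
  s <- c(20000L, 20200L, 20400L); e <- s + 99L
  add_gene("900002", "SCOD1", "11", "+", s, e, 20099L, 20450L,
           "NM_900002.1", "NP_900002.1")
  # minus strand, 5 exons; transcription intron 4 (between genomic exons 2
  # and 1) is 26 bp
  s <- c(30000L, 30126L, 30326L, 30526L, 30726L); e <- s + 99L
  add_gene("900003", "SINT26", "22", "-", s, e, 30150L, 30800L,
           "NM_900003.1", "NP_900003.1")
  # plus strand, 3 exons; intron 2 exactly 30 bp (40300..40329)
  s <- c(40000L, 40200L, 40330L); e <- s + 99L
  add_gene("900004", "SINT30", "12", "+", s, e, 40050L, 40400L,
           "NM_900004.1", "NP_900004.1")
  # mono-exonic
  add_gene("900005", "MONO1", "3", "+", 50000L, 50999L, 50100L, 50700L,
           "NM_900005.1", "NP_900005.1")
  # 363 exons of 100 bp separated by 50-bp introns
  s <- 100000L + (0:362) * 150L; e <- s + 99L
  add_gene("900006", "MAXEX1", "2", "+", s, e, 100010L, max(e) - 10L,
           "NM_900006.1", "NP_900006.1")
  sort_annotation_set(annotation_set(
    do.call(rbind, genes), do.call(rbind, txs), do.call(rbind, exs),
    provenance = list(source_format = "edge_fixture")
  ))
}
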