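# Assembly of the full descriptive-statistics report (gene, mRNA, exon,
# coding-exon and intron blocks, raw and non-redundant) and comparison of
# two reports across annotation releases.

#' Build the full statistics report for a curated annotation set
#'
#' Computes every block of the two summary tables this package produces:
#' gene counts (total, per chromosome with extremes, mean per chromosome
#' using the fixed divisor 24) and gene length stats; mRNA counts and
#' whole-transcript/5' UTR/CDS/3' UTR length stats; and, for exons,
#' coding-exon portions and introns, raw and non-redundant entry counts,
#' per-transcript count stats, length stats and not-last-exon variants,
#' with labelled extremes.
#'
#' @param set A curated [annotation_set] (run [apply_curation()] first; the
#'   function itself applies no filtering).
#' @param gt Optional precomputed [build_gene_table()] result.
#' @param tsum Optional precomputed [transcript_summaries()] result.
#' @return Object of class `stats_report` (a nested list of blocks whose
#'   leaves are scalars, named count vectors and `summary_stats` objects).
#' @export
build_report <- function(set, gt = NULL, tsum = NULL) {
  set <- sort_annotation_set(set)
  if (is.null(gt)) gt <- build_gene_table(set)
  if (is.null(tsum)) tsum <- transcript_summaries(set)
  g <- set$genes
  tx <- set$transcripts

  chrom <- per_chromosome_counts(set)
  gene_labels <- paste0(g$symbol, ", chr", g$chromosome)
  genes_block <- list(
    n = nrow(g),
    per_chromosome = chrom$counts,
    min_chromosomes = chrom$min_chromosomes, min_count = chrom$min_count,
    max_chromosomes = chrom$max_chromosomes, max_count = chrom$max_count,
    mean_per_chromosome = if (nrow(g)) mean_from_totals(nrow(g), 24L, 0L)
      else NA_real_,
    length = summarize_values(
      if (nrow(g)) interval_length(g$gene_start, g$gene_end) else numeric(0),
      gene_labels
    )
  )

  tx_sym <- g$symbol[match(tsum$gene_id, g$gene_id)]
  tx_chr <- g$chromosome[match(tsum$gene_id, g$gene_id)]
  tx_labels <- paste0(tx_sym, ", chr", tx_chr)
  mrnas_block <- list(
    n = nrow(tx),
    n_nm = sum(startsWith(tx$accession, "NM_")),
    length = summarize_values(tsum$transcript_len, tx_labels),
    utr5 = summarize_values(tsum$utr5_len, tx_labels),
    cds = summarize_values(tsum$cds_len, tx_labels),
    utr3 = summarize_values(tsum$utr3_len, tx_labels)
  )

  exon_lab <- paste0(gt$symbol, ", E", gt$exon_serial)
  intron_lab <- paste0(gt$symbol, ", I", gt$intron_serial)
  nr_ex <- gt$nr_exon != ""
  has_cd <- !is.na(gt$coding_length)
  nr_cd <- gt$nr_coding != ""
  has_in <- !is.na(gt$intron_length)
  nr_in <- gt$nr_intron != ""

  exons_block <- list(
    raw = list(
      n = nrow(gt),
      per_transcript = per_transcript_count_stats(set, "exon", tsum),
      length = summarize_values(gt$exon_length, exon_lab),
      not_last = not_last_exon_stats(gt, "exon", nonredundant = FALSE)
    ),
    nonredundant = list(
      n = sum(nr_ex),
      length = summarize_values(gt$exon_length[nr_ex], exon_lab[nr_ex]),
      not_last = not_last_exon_stats(gt, "exon", nonredundant = TRUE)
    )
  )
  coding_block <- list(
    raw = list(
      n = sum(has_cd),
      per_transcript = per_transcript_count_stats(set, "coding", tsum),
      length = summarize_values(gt$coding_length[has_cd], exon_lab[has_cd]),
      not_last = not_last_exon_stats(gt, "coding", nonredundant = FALSE)
    ),
    nonredundant = list(
      n = sum(nr_cd),
      length = summarize_values(gt$coding_length[nr_cd], exon_lab[nr_cd]),
      not_last = not_last_exon_stats(gt, "coding", nonredundant = TRUE)
    )
  )
  introns_block <- list(
    raw = list(
      n = sum(has_in),
      per_transcript = per_transcript_count_stats(set, "intron", tsum),
      length = summarize_values(gt$intron_length[has_in], intron_lab[has_in])
    ),
    nonredundant = list(
      n = sum(nr_in),
      length = summarize_values(gt$intron_length[nr_in], intron_lab[nr_in])
    )
  )

  structure(
    list(genes = genes_block, mrnas = mrnas_block, exons = exons_block,
         coding_exons = coding_block, introns = introns_block),
    class = "stats_report"
  )
}

#' Flatten a report to a named numeric vector
#'
#' Walks the nested report and extracts every numeric cell under a
#' dot-separated path (e.g. `exons.raw.length.mean`,
#' `genes.per_chromosome.X`). Labels and other text are dropped.
#'
#' @param r A `stats_report` (or ground-truth report of the same shape).
#' @return Named numeric vector.
#' @export
flatten_report <- function(r) {
  out <- numeric()
  walk <- function(x, path) {
    if (inherits(x, "summary_stats")) {
      x <- unclass(x)[c("n", "median", "mean", "sd", "min", "max", "total")]
    }
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], c(path, nm))
    } else if (is.numeric(x) || is.integer(x)) {
      if (length(x) == 1L && is.null(names(x))) {
        out[[paste(path, collapse = ".")]] <<- as.numeric(x)
      } else if (!is.null(names(x))) {
        for (nm in names(x)) {
          out[[paste(c(path, nm), collapse = ".")]] <<- as.numeric(x[[nm]])
        }
      }
    }
  }
  walk(unclass(r), character())
  out
}

#' Compare two statistics reports
#'
#' Emits one row per numeric metric with the old and new values, the
#' absolute change and the percent change (empty where the old value is not
#' positive). Metrics present in only one report are listed with status
#' `missing_in_old` / `missing_in_new` rather than erroring.
#'
#' @param old,new `stats_report` objects (e.g. two annotation releases).
#' @param decimals Decimal places for the percent change (default 1).
#' @return data.frame with columns `metric`, `old`, `new`, `delta`,
#'   `pct_change`, `status`.
#' @export
compare_reports <- function(old, new, decimals = 1L) {
  a <- flatten_report(old)
  b <- flatten_report(new)
  metrics <- union(names(a), names(b))
  av <- a[metrics]; bv <- b[metrics]
  status <- ifelse(!(metrics %in% names(a)), "missing_in_old",
                   ifelse(!(metrics %in% names(b)), "missing_in_new", "ok"))
  delta <- bv - av
  pct <- rep(NA_real_, length(metrics))
  can <- status == "ok" & !is.na(av) & !is.na(bv) & av > 0
  pct[can] <- vapply(which(can),
                     function(i) percent_change(av[i], bv[i], decimals), 1)
  data.frame(metric = metrics, old = unname(av), new = unname(bv),
             delta = unname(delta), pct_change = pct, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Serialize a report as JSON
#'
#' @param r A `stats_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(r, path = NULL) {
  json <- jsonlite::toJSON(unclass_recursive(r), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path, useBytes = TRUE)
  invisible(json)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

fmt_bp <- function(x, digits = 0L) {
  if (is.null(x) || is.na(x)) return("-")
  formatC(round_half_away(x, digits), format = "f", digits = digits,
          big.mark = ",")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("<stats_report>\n")
  cat(sprintf("Genes: %d entries; mean per chromosome %s; length median %s bp, mean %s bp, total %s bp\n",
              x$genes$n, fmt_bp(x$genes$mean_per_chromosome),
              fmt_bp(x$genes$length$median), fmt_bp(x$genes$length$mean),
              fmt_bp(x$genes$length$total)))
  cat(sprintf("mRNAs: %d entries (%d NM_); length median %s bp, mean %s bp, total %s bp\n",
              x$mrnas$n, x$mrnas$n_nm, fmt_bp(x$mrnas$length$median),
              fmt_bp(x$mrnas$length$mean), fmt_bp(x$mrnas$length$total)))
  blk <- function(name, b, per_tx = TRUE) {
    cat(sprintf("%s: %d raw / %d non-redundant entries\n",
                name, b$raw$n, b$nonredundant$n))
    if (per_tx && b$raw$per_transcript$n > 0) {
      cat(sprintf("  per transcript: median %s, mean %s\n",
                  fmt_bp(b$raw$per_transcript$median, 1L),
                  fmt_bp(b$raw$per_transcript$mean, 1L)))
    }
    cat(sprintf("  length: median %s / NR %s bp; mean %s / NR %s bp; total %s / NR %s bp\n",
                fmt_bp(b$raw$length$median), fmt_bp(b$nonredundant$length$median),
                fmt_bp(b$raw$length$mean), fmt_bp(b$nonredundant$length$mean),
                fmt_bp(b$raw$length$total), fmt_bp(b$nonredundant$length$total)))
    if (b$raw$length$n > 0) {
      cat(sprintf("  shortest %s bp (%s); longest %s bp (%s)\n",
                  fmt_bp(b$raw$length$min), b$raw$length$min_label,
                  fmt_bp(b$raw$length$max), b$raw$length$max_label))
    }
  }
  blk("Exons", x$exons)
  blk("Coding exons", x$coding_exons)
  blk("Introns", x$introns)
  invisible(x)
}
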