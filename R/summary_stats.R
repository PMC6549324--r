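# Descriptive-statistics primitives: spreadsheet-convention summaries
# (sample SD, midpoint median), half-away-from-zero rounding, means derived
# from printed totals, release-over-release percent changes, and the
# filtered variants (not-last-exon, per-transcript counts, per-chromosome
# gene counts).

#' Round half away from zero
#'
#' Spreadsheet-style rounding (0.5 always moves away from zero), as opposed
#' to R's round-half-even. All printed lengths and ratios in this package
#' use this rule.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Summarize a distribution of lengths or counts
#'
#' Computes n, median (midpoint rule: mean of the two central order
#' statistics for even n), mean, sample SD (n - 1 denominator; empty when
#' n = 1), min, max and total. Optional labels identify the extreme
#' features; ties are all reported, sorted, joined by "; ".
#'
#' @param values Numeric vector.
#' @param labels Optional character vector parallel to `values` naming each
#'   feature (e.g. `"GSTP1, E1"`).
#' @param population_sd Use the population (n denominator) SD instead of
#'   the sample SD (default `FALSE`).
#' @return Object of class `summary_stats`; for empty input an empty-stats
#'   marker with `n = 0` and `NA` elsewhere (never zeros).
#' @export
summarize_values <- function(values, labels = NULL, population_sd = FALSE) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) {
    return(structure(
      list(n = 0L, median = NA_real_, mean = NA_real_, sd = NA_real_,
           min = NA_real_, max = NA_real_, total = NA_real_,
           min_label = NA_character_, max_label = NA_character_),
      class = "summary_stats"
    ))
  }
  s <- if (n == 1L) NA_real_ else stats::sd(values)
  if (population_sd && n > 1L) s <- s * sqrt((n - 1) / n)
  lab <- function(target) {
    if (is.null(labels)) return(NA_character_)
    paste(sort(unique(labels[values == target])), collapse = "; ")
  }
  structure(
    list(
      n = n,
      median = stats::median(values),
      mean = sum(values) / n,
      sd = s,
      min = min(values),
      max = max(values),
      total = sum(values),
      min_label = lab(min(values)),
      max_label = lab(max(values))
    ),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  if (x$n == 0L) {
    cat("<summary_stats> empty\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<summary_stats> n=%d median=%g mean=%g sd=%s min=%g max=%g total=%g\n",
    x$n, x$median, x$mean,
    if (is.na(x$sd)) "-" else sprintf("%g", x$sd), x$min, x$max, x$total
  ))
  invisible(x)
}

#' Mean from a printed total and count
#'
#' The ratio convention used by the summary tables: `total / n` rounded
#' half-away-from-zero to `decimals` places. This is how, e.g., a mean gene
#' length is recovered from a printed total length and entry count, or the
#' mean genes per chromosome from a gene count and the fixed divisor 24
#' (22 autosomes + X + Y).
#'
#' @param total Numeric total.
#' @param n Positive count (divisor).
#' @param decimals Decimal places of the result (default 0).
#' @return The rounded mean.
#' @export
mean_from_totals <- function(total, n, decimals = 0L) {
  if (is.na(n) || n <= 0) stop("mean undefined for n <= 0", call. = FALSE)
  round_half_away(total / n, decimals)
}

#' Percent change between two release values
#'
#' `100 * (new - old) / old`, rounded half-away-from-zero.
#'
#' @param old,new Numeric values; `old` must be positive.
#' @param decimals Decimal places (default 1).
#' @return Percent change.
#' @export
percent_change <- function(old, new, decimals = 1L) {
  if (is.na(old) || old <= 0) {
    stop("percent change undefined for old <= 0", call. = FALSE)
  }
  round_half_away(100 * (new - old) / old, decimals)
}

canonical_chromosomes <- function() c(as.character(1:22), "X", "Y", "MT")

#' Gene counts per chromosome
#'
#' Counts genes by chromosome text key and reports the chromosomes with the
#' fewest and most genes (ties all reported).
#'
#' @param set An [annotation_set] (typically curated).
#' @return List with `counts` (named integer vector in canonical chromosome
#'   order, then any other keys alphabetically), `min_chromosomes`,
#'   `min_count`, `max_chromosomes`, `max_count` (`NULL`s for an empty set).
#' @export
per_chromosome_counts <- function(set) {
  chr <- set$genes$chromosome
  if (!length(chr)) {
    return(list(counts = stats::setNames(integer(), character()),
                min_chromosomes = NULL, min_count = NULL,
                max_chromosomes = NULL, max_count = NULL))
  }
  tab <- table(chr)
  canon <- canonical_chromosomes()
  keys <- c(intersect(canon, names(tab)),
            sort(setdiff(names(tab), canon)))
  counts <- stats::setNames(as.integer(tab[keys]), keys)
  list(
    counts = counts,
    min_chromosomes = names(counts)[counts == min(counts)],
    min_count = min(counts),
    max_chromosomes = names(counts)[counts == max(counts)],
    max_count = max(counts)
  )
}

#' Length statistics excluding last exons
#'
#' The last exon of a transcript is usually its longest (it carries the 3'
#' UTR), so the exon and coding-exon length tables are also summarized with
#' last records excluded. For exons the exclusion uses the last-exon flag;
#' for coding portions, the last-coding-exon flag.
#'
#' @param gt Feature table from [build_gene_table()].
#' @param feature_class `"exon"` or `"coding"`.
#' @param nonredundant Restrict to non-redundant representatives?
#' @return A [summarize_values()] `summary_stats` object (empty-stats marker
#'   when every record is a last exon, e.g. an all-mono-exonic set).
#' @export
not_last_exon_stats <- function(gt, feature_class = c("exon", "coding"),
                                nonredundant = FALSE) {
  feature_class <- match.arg(feature_class)
  if (feature_class == "exon") {
    keep <- !gt$last_exon
    len <- gt$exon_length
    nr <- gt$nr_exon
    lab <- paste0(gt$symbol, ", E", gt$exon_serial)
  } else {
    keep <- !gt$last_coding_exon & !is.na(gt$coding_length)
    len <- gt$coding_length
    nr <- gt$nr_coding
    lab <- paste0(gt$symbol, ", E", gt$exon_serial)
  }
  if (nonredundant) keep <- keep & nr != ""
  summarize_values(len[keep], lab[keep])
}

#' Per-transcript feature-count statistics
#'
#' Distribution of exons, coding exons or introns per transcript. Intron
#' counts are `n_exons - 1`; their minimum is taken excluding mono-exonic
#' transcripts (which have no introns), while median/mean/SD/total cover
#' all transcripts. Extreme labels report how many transcripts and genes
#' attain the minimum, and the gene symbol(s) attaining the maximum.
#'
#' @param set An [annotation_set].
#' @param feature_class `"exon"`, `"coding"` or `"intron"`.
#' @param tsum Optional precomputed [transcript_summaries()] table.
#' @return A `summary_stats` object (empty marker when no transcript has
#'   the feature, e.g. introns in an all-mono-exonic set).
#' @export
per_transcript_count_stats <- function(set,
                                       feature_class = c("exon", "coding", "intron"),
                                       tsum = NULL) {
  feature_class <- match.arg(feature_class)
  if (is.null(tsum)) tsum <- transcript_summaries(set)
  values <- switch(feature_class,
                   exon = tsum$n_exons,
                   coding = tsum$n_coding_exons,
                   intron = tsum$n_introns)
  keep <- !is.na(values)
  values <- values[keep]
  gid <- tsum$gene_id[keep]
  sym <- set$genes$symbol[match(gid, set$genes$gene_id)]
  if (feature_class == "intron" && (!length(values) || all(values == 0L))) {
    return(summarize_values(numeric(0)))
  }
  ss <- summarize_values(values)
  min_pool <- if (feature_class == "intron") values[values > 0L] else values
  ss$min <- if (length(min_pool)) min(min_pool) else NA_real_
  at_min <- values == ss$min
  ss$min_label <- sprintf("%d transcripts; %d genes",
                          sum(at_min), length(unique(gid[at_min])))
  ss$max_label <- paste(sort(unique(sym[values == ss$max])), collapse = "; ")
  ss
}
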