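# Record-selection policy defining the curated analysis set: nuclear
# protein-coding genes with human-curated (REVIEWED/VALIDATED) RefSeq status
# at both gene and transcript level, present in the current annotation
# release, with at least one qualifying curated mRNA (NM_ accession).

#' Construct a curation policy
#'
#' Defaults encode the curated-set definition used throughout this package:
#' protein-coding gene type; REVIEWED or VALIDATED RefSeq status at gene and
#' transcript level; current-annotation records only; mitochondrial
#' chromosome excluded (nuclear genes only); transcripts must carry an
#' `NM_`-prefixed accession (curated mRNAs, not XM_ model predictions).
#' `NA` statuses always fail the status rules.
#'
#' @param allowed_gene_types Character set of gene types kept.
#' @param allowed_gene_statuses Character set of gene RefSeq statuses kept.
#' @param allowed_transcript_statuses Character set of transcript RefSeq
#'   statuses kept.
#' @param require_current_annotation Drop records flagged as not in the
#'   current annotation release?
#' @param exclude_chromosomes Chromosome names to drop (default `"MT"`).
#' @param transcript_accession_prefix Required accession prefix for
#'   transcripts (default `"NM_"`).
#' @return Object of class `curation_policy`.
#' @export
curation_policy <- function(allowed_gene_types = "protein-coding",
                            allowed_gene_statuses = c("REVIEWED", "VALIDATED"),
                            allowed_transcript_statuses = c("REVIEWED", "VALIDATED"),
                            require_current_annotation = TRUE,
                            exclude_chromosomes = "MT",
                            transcript_accession_prefix = "NM_") {
  if (!length(allowed_gene_types) || !length(allowed_gene_statuses) ||
      !length(allowed_transcript_statuses)) {
    stop("policy type/status sets must be non-empty", call. = FALSE)
  }
  structure(
    list(
      allowed_gene_types = allowed_gene_types,
      allowed_gene_statuses = allowed_gene_statuses,
      allowed_transcript_statuses = allowed_transcript_statuses,
      require_current_annotation = isTRUE(require_current_annotation),
      exclude_chromosomes = exclude_chromosomes,
      transcript_accession_prefix = transcript_accession_prefix
    ),
    class = "curation_policy"
  )
}

#' Apply a curation policy to an annotation set
#'
#' Genes are kept iff they pass the type, gene-status, currency and
#' chromosome rules AND have at least one transcript passing the
#' transcript-level rules (status plus accession prefix); a gene whose
#' transcripts all fail is removed entirely. Within kept genes only passing
#' transcripts are retained. Rules are applied in a fixed order -- gene type,
#' gene status, currency, chromosome, transcript level -- and a gene failing
#' several rules is counted once, at the first failing rule, so removal
#' accounting is reproducible. Filtering never errors.
#'
#' @param set An [annotation_set].
#' @param policy A [curation_policy].
#' @return List with elements `set` (the curated [annotation_set]) and
#'   `report` (a `filter_report`: input/retained counts and per-rule gene
#'   removal counts in application order, plus the count of transcripts
#'   removed inside kept genes and both transcript-counting modes:
#'   `n_retained_transcripts` and the `NM_`-prefix count `n_nm_mrnas`).
#' @export
apply_curation <- function(set, policy = curation_policy()) {
  stopifnot(inherits(set, "annotation_set"), inherits(policy, "curation_policy"))
  g <- set$genes
  tx <- set$transcripts

  ok_status <- function(x, allowed) !is.na(x) & x %in% allowed
  tx_pass <- ok_status(tx$transcript_refseq_status,
                       policy$allowed_transcript_statuses) &
    startsWith(tx$accession, policy$transcript_accession_prefix)
  gene_has_tx <- g$gene_id %in% tx$gene_id[tx_pass]

  fail_rule <- rep(NA_character_, nrow(g))
  mark <- function(fail_rule, cond, rule) {
    ifelse(is.na(fail_rule) & cond, rule, fail_rule)
  }
  fail_rule <- mark(fail_rule, !(g$gene_type %in% policy$allowed_gene_types),
                    "gene_type")
  fail_rule <- mark(fail_rule,
                    !ok_status(g$gene_refseq_status, policy$allowed_gene_statuses),
                    "gene_refseq_status")
  if (policy$require_current_annotation) {
    fail_rule <- mark(fail_rule, !g$in_current_annotation | !g$live_status,
                      "not_current")
  }
  fail_rule <- mark(fail_rule, g$chromosome %in% policy$exclude_chromosomes,
                    "chromosome")
  fail_rule <- mark(fail_rule, !gene_has_tx, "no_qualifying_transcript")

  keep_gene <- is.na(fail_rule)
  kept_ids <- g$gene_id[keep_gene]
  keep_tx <- tx$gene_id %in% kept_ids & tx_pass
  removed_tx_in_kept <- sum(tx$gene_id %in% kept_ids & !tx_pass)

  rules <- c("gene_type", "gene_refseq_status", "not_current", "chromosome",
             "no_qualifying_transcript")
  removed <- vapply(rules, function(r) sum(fail_rule == r, na.rm = TRUE), 1L)

  curated <- annotation_set(
    g[keep_gene, , drop = FALSE],
    tx[keep_tx, , drop = FALSE],
    set$exons[set$exons$accession %in% tx$accession[keep_tx], , drop = FALSE],
    provenance = c(set$provenance, list(curated = TRUE)),
    validate = FALSE
  )
  report <- structure(
    list(
      n_input_genes = nrow(g),
      n_input_transcripts = nrow(tx),
      removed_genes = removed,
      removed_transcripts_in_kept_genes = removed_tx_in_kept,
      n_retained_genes = sum(keep_gene),
      n_retained_transcripts = sum(keep_tx),
      n_nm_mrnas = sum(keep_tx &
                         startsWith(tx$accession, "NM_"))
    ),
    class = "filter_report"
  )
  list(set = curated, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat(sprintf("  input:    %d genes, %d transcripts\n",
              x$n_input_genes, x$n_input_transcripts))
  cat("  genes removed (first failing rule, in application order):\n")
  for (r in names(x$removed_genes)) {
    cat(sprintf("    %-26s %d\n", r, x$removed_genes[[r]]))
  }
  cat(sprintf("  transcripts removed within kept genes: %d\n",
              x$removed_transcripts_in_kept_genes))
  cat(sprintf("  retained: %d genes, %d transcripts (%d NM_ mRNAs)\n",
              x$n_retained_genes, x$n_retained_transcripts, x$n_nm_mrnas))
  invisible(x)
}
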