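#!/usr/bin/env Rscript

# Step 4: release-over-release comparison.
#
# Two comparisons are run. First, the published totals for the curated
# human nuclear protein-coding set in the 2016 and 2019 RefSeq-derived
# releases are fed to the percent-change operation: gene count 18,255 ->
# 19,116, non-redundant transcriptome space 53,827,863 -> 59,281,518 bp,
# raw exon count 412,641 -> 562,164. Second, a full report-vs-report delta
# table is computed between the simulated release of step 1 and a second,
# larger simulated release standing in for a later annotation update.

suppressPackageStartupMessages(library(genefeatr))

cat("Published 2016 -> 2019 changes (percent, half-away-from-zero, 1 dp):\n")
published <- data.frame(
  metric = c("curated genes", "non-redundant transcriptome bp", "raw exons"),
  old = c(18255, 53827863, 412641),
  new = c(19116, 59281518, 562164)
)
published$pct_change <- mapply(percent_change, published$old, published$new)
print(published, row.names = FALSE)

if (!file.exists("results/simulated_release.gff3")) {
  stop("run analysis/01_simulate.R first")
}
old_set <- apply_curation(read_gff3("results/simulated_release.gff3"))$set
new_gen <- generate_annotation(
  generator_params(n_genes = 230L, mean_isoforms = 3.1, seed = 20220101L)
)
new_set <- apply_curation(new_gen$set)$set

cmp <- compare_reports(build_report(old_set), build_report(new_set))
write.table(cmp, "results/release_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
headline <- cmp[cmp$metric %in% c(
  "genes.n", "mrnas.n", "exons.raw.n", "exons.nonredundant.length.total",
  "introns.raw.length.mean"
), ]
cat("\nSimulated release comparison (headline metrics):\n")
print(headline, row.names = FALSE)
cat(sprintf("\nWrote results/release_comparison.tsv (%d metrics)\n",
            nrow(cmp)))
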