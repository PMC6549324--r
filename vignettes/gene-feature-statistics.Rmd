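---
title: "Gene feature derivation and descriptive statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene feature derivation and descriptive statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefeatr)
```

## The problem

Genome browsers present gene annotation as records to look at, not as a
database to compute on. Questions as simple as "what is the median human
intron length in curated protein-coding genes?" require flattening the
gene → mRNA → exon/CDS hierarchy into tables on which spreadsheet-style
statistics can be taken, after restricting to a curated, non-redundant
record set. `genefeatr` implements that flattening and the statistics on
top of it:

1. **Import** gene models from GFF3/GTF (or this package's own three-table
   TSV dialect) into an `annotation_set`: three keyed data frames (genes,
   transcripts, exons) holding 1-based, inclusive genomic coordinates.
2. **Curate** with `apply_curation()`: keep nuclear protein-coding genes
   with human-curated (REVIEWED/VALIDATED) RefSeq status at gene and
   transcript level, present in the current annotation release, with at
   least one `NM_` mRNA; drop everything else with per-rule accounting.
3. **Derive** per-exon features with `build_gene_table()`: companion
   introns, coding-exon portions, UTR/CDS splits, serials, last-exon flags
   and non-redundancy labels.
4. **Summarize** with `build_report()`: counts and length distributions
   (n, median, mean, SD, min, max, total) for genes, mRNAs, exons, coding
   exons and introns, raw and non-redundant, plus per-transcript counts
   and not-last-exon variants; compare releases with `compare_reports()`.

## Coordinate model and derivation rules

Coordinates are 1-based and inclusive at both ends, so
`length = end − start + 1`. Intervals are stored genomically
(`start ≤ end`) on both strands; transcription order is carried by serial
numbers, which on the minus strand run genomically right to left. This
makes minus-strand arithmetic explicit rather than implicit in coordinate
order. Chromosomes are text everywhere ("1"… "22", "X", "Y", "MT") so sex
chromosomes can never be coerced to numbers by downstream tools.

The derivation rules, each of which is both unit-tested against hand-worked
examples and property-tested over random models:

* **Introns.** A transcript with *n* exons has exactly *n* − 1 introns;
  intron *i* fills the genomic gap between exons *i* and *i* + 1 in
  transcription order. Introns are exported as *companions* of their
  upstream exon's row, so last-exon rows never carry intron data. Adjacent
  exons with no gap are treated as an annotation defect and rejected.
* **Coding portions.** The CDS span runs from the first to the last coding
  base **including the stop codon**; a GTF `stop_codon` feature is merged
  into the span on read, and GFF3 CDS features are assumed stop-inclusive
  (a reader flag covers dialects that exclude it). The coding portion of
  an exon is its intersection with the CDS span; portions always sum to
  the CDS length. A CDS starting on the last base of an exon legitimately
  produces a 1-bp coding exon.
* **UTR/CDS split.** In spliced (mRNA) coordinates,
  `utr5 + cds + utr3 = transcript length`, with 5′ and 3′ assigned by
  strand. The genomic UTR columns of the export give bounding spans of the
  exonic UTR bases.
* **Last-exon flags.** Exactly one exon per transcript is last (highest
  serial). Because a 3′ UTR can occupy whole exons, the *last coding* exon
  can precede the last exon; the export therefore carries two columns,
  `Last_Exon` (controls the companion-intron rule) and `Last_Coding_Exon`
  (drives the coding "not last" statistics).
* **Non-redundancy.** Isoforms share features; each identity group —
  exact coordinate equality scoped per feature class, chromosome accession
  and strand — gets exactly one labelled representative: `Yes—Unique` for
  singletons, `Yes—Merged` for recurring elements, blank otherwise. The
  representative is the first row under the deterministic
  (gene, transcript accession, serial) sort, so outputs are reproducible;
  partially overlapping features are distinct elements, since fuzzy
  merging would change totals unpredictably. Coding portions are collapsed
  by *coding-portion* coordinates, not host-exon coordinates: two isoforms
  can share an exon yet differ in where the CDS enters it, and the
  coding-length totals must reflect that.
* **Short introns.** Canonical splicing produces no intron under 30 bp, so
  `flag_short_introns()` reports non-redundant introns below the threshold
  for manual review — 1–3 bp values as likely parsing artifacts, the rest
  as non-canonical excision candidates (the known 26-bp IRE1-mediated
  XBP1 excision is the archetype). Nothing is removed automatically, and
  flagged introns stay in the statistics, matching how the printed totals
  of curated releases are computed.

## Statistical conventions

Summaries follow spreadsheet conventions, because the reference tables this
package reproduces were computed that way: median by the midpoint rule,
**sample** SD (n − 1; a population-SD switch exists), SD reported empty for
n = 1, empty inputs reported as an empty marker rather than zeros. All
printed ratios round **half away from zero** (`round_half_away()`), the
spreadsheet default, not R's round-half-even: lengths to integer bp,
per-transcript counts and percent changes to one decimal. Mean genes per
chromosome always divides by the fixed 24 (22 autosomes + X + Y),
regardless of which chromosomes are present. Extreme values carry feature
labels (e.g. `"GSTP1, E1"`), with ties all reported in sorted order.

Fed the published totals of the January-2019 curated human set, these
conventions reproduce every printed derived value (mean gene length
66,646 bp; 797 genes/chromosome; mean mRNA 3,522 bp; exon means
311/371 bp raw/non-redundant; coding-exon means 160/171 bp; intron means
6,938/7,397 bp; 11.3 exons per transcript; the 10.1% and 36.2% release
increases) — `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` recompute all of them.

## The synthetic generator and what passing tests show

`generate_annotation()` produces seeded annotation sets with exact ground
truth, counted as the models are emitted rather than re-derived through the
pipeline. Study conditions are fixed in `generator_params()` and were
chosen once to emulate the curated human set:

* exon lengths log-normal with median 131 bp and sdlog 1.31 (matching the
  published mean/median ratio 311/131); intron lengths log-normal with
  median 1,747 bp and sdlog 1.66 (ratio 6,938/1,747), floored at 30 bp
  since shorter canonical introns do not occur;
* ~9 exons per transcript (Poisson-based, `2 + rpois(7.5)` templates with
  isoform-level exon skipping), geometric isoform counts with mean 2.6
  (≈ 49,632 mRNAs / 19,116 genes), mono-exonic gene fraction 0.055
  (≈ 1,068 / 19,116);
* 5′/3′ UTR log-normal medians 170/800 bp, CDS kept ≥ 3 bp and trimmed to
  a codon multiple where room allows; minus-strand fraction 0.5;
* contaminant gene fractions exercising every curation rule: pseudogene
  0.10, MODEL status 0.05, non-current 0.03, mitochondrial 0.02, XM-only
  0.03, plus an 8% chance that a secondary isoform of a clean gene is an
  XM_/MODEL prediction.

One integer seed drives one explicit RNG stream (the session RNG state is
saved and restored), so generation is byte-reproducible. Distribution
families are pragmatic choices to hit the published medians, not claims
about biology. The generator does **not** emulate realistic chromosome
gene density, sequence content, overlapping genes, trans-splicing,
non-coding RNA classes, or the exact human length distributions — its
per-transcript coding-exon counts, for instance, run lower than the human
8.0 median because UTR draws are independent of transcript length.
Passing recovery tests therefore demonstrate that the pipeline's
arithmetic, filtering, collapsing and accounting are exact on data of the
assumed *structure*; they do not validate the upstream annotation itself.

The central recovery test runs the full pipeline on 200-gene sets for five
seeds and requires every integer cell of the report to equal the ground
truth exactly and every real cell to 1e-9 relative; problem sizes
(200 genes, ~520 transcripts, ~4,500 exon rows per seed; 100-seed property
sweeps over single transcripts) keep the whole suite in the tens of
seconds while still exercising multi-isoform sharing and both strands.
`make_edge_fixtures()` complements it with hand-built boundary shapes — a
2-bp exon, a 1-bp coding exon, 26-bp and 30-bp introns straddling the
flagging threshold, a mono-exonic gene, a 363-exon transcript — all
hand-derivable from their coordinates.

## Numerical and design choices

* **Ties** in extremes: all tied features are reported, sorted by label.
* **Degenerate inputs**: empty sets produce header-only exports and
  empty-stats markers; an all-mono-exonic set has no intron statistics
  rather than zeros; absent coding/intron cells are empty strings, never 0.
* **Gene span**: the explicit gene feature is used when the input provides
  one; otherwise the union of transcript spans. Multi-chromosome or
  multi-strand gene models are rejected outright.
* **Counting modes**: curated releases have been described both by their
  post-filter transcript count and by their `NM_`-accession mRNA count,
  and published counts of the two kinds disagree (46,932 vs 49,632 for the
  2019 set); the filter report exposes both (`n_retained_transcripts`,
  `n_nm_mrnas`) instead of guessing. Under the default policy they
  coincide on this package's data model.
* **Removal accounting** applies rules in a fixed order (type → gene
  status → currency → chromosome → transcript level) and counts each gene
  once at its first failing rule, making intermediate counts reproducible
  even though only final counts are usually published.
* **Absent metadata** is conservative: missing RefSeq status attributes
  become `NA`, which the default policy rejects; missing currency/liveness
  attributes default to current/live, since the upstream flag is an
  explicit exclusion annotation.
* The three-table export is TSV (UTF-8, Unix newlines) rather than xlsx:
  a bit-exact, diffable test surface with the same column inventory
  (documented in `inst/extdata/data_dictionary.tsv`). Column order is
  fixed by this package's dialect; byte compatibility with any particular
  spreadsheet deposit is not claimed.

## Worked example

```{r example, eval = FALSE}
gen <- generate_annotation(generator_params(n_genes = 200, seed = 20190105))
cur <- apply_curation(gen$set)
print(cur$report)
report <- build_report(cur$set)
print(report)
# exact recovery of the generator's expected cells
max(abs(flatten_report(report) - flatten_report(gen$truth$report)),
    na.rm = TRUE)
```

The numbered drivers under `analysis/` run this workflow from the GFF3
level up and leave their outputs under `results/`.

## Limitations

Real-annotation effects outside the generator's structure — trans-spliced
or multi-chromosome models, CDS exceptions, exotic biotypes, chromosome
patches and alt loci — are either rejected explicitly or out of scope.
Statistics are descriptive only; no inference is attempted. Alignment-level
validation of annotation (e.g. spliced re-alignment of mRNAs) is outside
the package: `flag_short_introns()` marks candidates but cannot decide
whether they are artifacts.
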