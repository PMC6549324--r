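#!/usr/bin/env Rscript

# Step 1: simulate an annotation release.
#
# Generates a seeded synthetic human-style annotation set (200 nuclear
# protein-coding genes plus contaminants: pseudogenes, MODEL-status genes,
# non-current records, mitochondrial genes and XM_-only genes) together with
# its exact ground truth, and writes the models as GFF3 plus the expected
# statistics as JSON. Later steps re-ingest the GFF3 so the whole pipeline
# is exercised from the file format up.

suppressPackageStartupMessages(library(genefeatr))

out_dir <- "results"
if (!dir.exists(out_dir)) dir.create(out_dir)

params <- generator_params(n_genes = 200L, seed = 20190105L)
gen <- generate_annotation(params)

cat("Simulated release:\n")
print(gen$set)
print(gen$truth)

write_gff3(gen$set, file.path(out_dir, "simulated_release.gff3"))
jsonlite::write_json(
  lapply(unclass(gen$truth), function(x) x),
  file.path(out_dir, "simulated_ground_truth.json"),
  auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
)
cat(sprintf("\nWrote %s and %s\n",
            file.path(out_dir, "simulated_release.gff3"),
            file.path(out_dir, "simulated_ground_truth.json")))
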