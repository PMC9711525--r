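#!/usr/bin/env Rscript
# Generate the synthetic cohorts used by the downstream analyses:
# an APS1-like cohort (128 cases / 186 healthy controls / 8 mock-IP,
# 10 disease antigens spiked at 100-fold enrichment, penetrance 0.3)
# and a matched null cohort with no disease antigens. Counts, maps,
# sample sheets and spike-in ground truth go to results/data/.

suppressPackageStartupMessages(library(phipkit))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (name in c("aps1_like", "null")) {
  ds <- make_fixture(name)
  dir.create(file.path(out, name), showWarnings = FALSE)
  write_count_matrix(ds$counts, file.path(out, name, "peptide_counts.tsv"))
  write.table(ds$map, file.path(out, name, "peptide_gene_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(ds$sheet, file.path(out, name, "sample_sheet.csv"), row.names = FALSE)
  write.table(ds$truth, file.path(out, name, "spike_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d peptides x %d samples, %d disease spike-in entries\n",
              name, nrow(ds$counts), ncol(ds$counts),
              sum(ds$truth$origin == "disease")))
}
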