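#!/usr/bin/env Rscript
# Shared-hit calling and the control-downsampling experiment. Hits are
# genes with Z >= 10 in >= 10% of cases, positive in < 2% of controls,
# at least one case at FC >= 50, and no control above the top case.
# Control sets of 5..150 are redrawn 10 times each; Z-scores are rebuilt
# against every downsampled reference. Requires 01 and 02.

suppressPackageStartupMessages(library(phipkit))

out <- "results/hits"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
read_mat <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  as.matrix(`rownames<-`(df[-1], df[[1]]))
}

sheet <- read_sample_sheet("results/data/aps1_like/sample_sheet.csv")
fc <- read_mat("results/enrichment/fold_change.tsv")
z <- read_mat("results/enrichment/zscore.tsv")
truth <- read.delim("results/data/aps1_like/spike_truth.tsv")
spiked <- unique(truth$gene_id[truth$origin == "disease"])

hits <- call_hits(z, fc, sheet, hit_criteria())
write.table(hits, file.path(out, "hit_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
passed <- hits$gene_id[hits$passed]
cat(sprintf("%d/%d spiked antigens recovered, %d false positives (of %d genes)\n",
            sum(passed %in% spiked), length(spiked),
            sum(!passed %in% spiked), nrow(hits)))

curve <- downsample_controls(fc, sheet, hit_criteria(),
                             sizes = c(5, 10, 25, 50, 100, 150),
                             reps = 10, seed = 20)
write.table(curve$summary, file.path(out, "downsampling_aps1_like.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(curve$summary)

# same experiment on the null cohort: every apparent hit is spurious
nsheet <- read_sample_sheet("results/data/null/sample_sheet.csv")
ncounts <- read_count_matrix("results/data/null/peptide_counts.tsv", "peptide")
nmap <- read_peptide_gene_map("results/data/null/peptide_gene_map.tsv")
nfc <- fold_change(normalize_counts(aggregate_to_gene(ncounts, nmap)), nsheet)
ncurve <- downsample_controls(nfc, nsheet, hit_criteria(),
                              sizes = c(5, 10, 25, 50, 100, 150),
                              reps = 10, seed = 20)
write.table(ncurve$summary, file.path(out, "downsampling_null.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("null cohort: apparent hits shrink toward zero as controls grow\n")
print(ncurve$summary)
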