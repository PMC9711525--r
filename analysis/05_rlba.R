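#!/usr/bin/env Rscript
# Orthogonal validation arithmetic: radioligand binding assay (RLBA)
# antibody indices on a synthetic plate. Index = (sample - mean blank) /
# (positive control - mean blank); positivity cutoff = healthy-control
# mean + 3 SD. The plate below is a synthetic stand-in with realistic
# scintillation counts.

suppressPackageStartupMessages(library(phipkit))

out <- "results/rlba"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

set.seed(5)
plate <- data.frame(
  role = c(rep("blank", 3), rep("positive_control", 2),
           rep("healthy_control", 12), rep("sample", 8)),
  sample_id = c(rep("", 5), paste0("hc", 1:12), paste0("pt", 1:8)),
  cpm = c(rnorm(3, 100, 8), rnorm(2, 2100, 60),
          rnorm(12, 110, 15),
          c(rnorm(3, 1500, 200), rnorm(5, 115, 20))))
plate$cpm <- round(pmax(plate$cpm, 0), 1)
write.csv(plate, file.path(out, "plate_synthetic.csv"), row.names = FALSE)

idx <- rlba_indices(plate)
calls <- call_positives(idx)
write.table(calls, file.path(out, "antibody_indices.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("positivity cutoff (healthy mean + 3 SD): %.4f\n",
            unique(calls$cutoff)))
pt <- calls[grepl("^pt", calls$sample_id), ]
cat(sprintf("%d/%d patient wells called antibody-positive\n",
            sum(pt$positive), nrow(pt)))
print(pt, row.names = FALSE)
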