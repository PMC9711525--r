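# phipkit

Post-sequencing analysis of PhIP-seq (phage immunoprecipitation
sequencing) autoantibody screens, for groups comparing disease cohorts
against large healthy-control cohorts with bead-only (mock-IP)
background samples.

PhIP-seq reads out, as sequencing counts, which peptides of a
programmed phage library a serum's antibodies pull down. Because every
serum — healthy or not — strongly enriches its own private set of
antigens, disease-associated autoantigens can only be recognized as
*shared, case-specific* signal against a sufficiently large control
cohort. `phipkit` implements that analysis:

- **Enrichment statistics.** Peptide counts are summed per gene, a 0.5
  read pseudocount is added, and counts become percentages of each
  sample's total. Fold change (FC) is each gene's percentage over its
  mean percentage in mock-IP samples. Z-scores standardize FC against
  the healthy controls, with each control scored leave-one-out against
  the others.
- **Hit calling.** A gene is a shared hit when Z ≥ 10 in ≥ 10% of
  cases, positive in < 2% of controls, at least one case reaches
  FC ≥ 50, and no control exceeds the top case (dominance).
- **Control downsampling.** Re-draws control subsets of 5–150 samples
  (10× each), rebuilds the Z-score reference per subset, and recounts
  apparent hits — quantifying how larger control cohorts strip away
  false positives.
- **Classification.** L1-penalized logistic regression on log10
  reads-per-100k features with stratified five-fold cross-validation
  and a pooled out-of-fold ROC/AUC.
- **RLBA validation statistics.** Radioligand binding assay antibody
  index `(sample − mean blank)/(positive control − mean blank)` with a
  healthy-mean + 3 SD positivity cutoff.
- **Synthetic data.** A seeded Dirichlet-multinomial generator with
  skewed background, private autoreactivities, mock-IP replicates, and
  spiked disease antigens with known penetrance and effect — the ground
  truth behind every end-to-end test.

## Worked example

```r
library(phipkit)

ds   <- make_fixture("aps1_like")        # 128 cases / 186 controls / 8 mock-IP
gene <- aggregate_to_gene(ds$counts, ds$map)
fc   <- fold_change(normalize_counts(gene), ds$sheet)
z    <- zscore(fc, ds$sheet)

hits <- call_hits(z, fc, ds$sheet, hit_criteria())
sum(hits$passed)
#> [1] 10
all(hits$gene_id[hits$passed] %in% ds$truth$gene_id[ds$truth$origin == "disease"])
#> [1] TRUE
```

The ten genes passing the criteria are exactly the ten spiked disease
antigens; no background or private-reactivity gene passes. Growing the
control cohort removes spurious hits (here on the matched null cohort,
which contains no disease signal):

```r
nul <- make_fixture("null")
nfc <- fold_change(normalize_counts(aggregate_to_gene(nul$counts, nul$map)), nul$sheet)
downsample_controls(nfc, nul$sheet, hit_criteria(), reps = 10, seed = 20)$summary
#>   size mean_hits   sd_hits
#> 1    5       3.7 1.5670212
#> 2   10       1.7 0.9486833
#> 3   25       0.1 0.3162278
#> 4   50       0.0 0.0000000
#> 5  100       0.0 0.0000000
#> 6  150       0.0 0.0000000
```

With 5 controls, a few background genes masquerade as shared hits;
by 25–50 controls they are gone — the case for large control cohorts.
Classification on the same cohort:

```r
fm <- build_features(gene, ds$sheet)
fit_evaluate(fm, folds = 5, seed = 1)$auc
#> [1] 0.9565776
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic
cohorts and write tables under `results/`:

1. `01_simulate.R` — generate the APS1-like and null cohorts.
2. `02_enrichment.R` — gene aggregation, FC, Z-scores, per-sample
   enrichment profiles.
3. `03_hitcalling.R` — shared-hit calling and the downsampling
   experiment on both cohorts.
4. `04_classifier.R` — cross-validated classifier, ROC points,
   coefficient ranking vs ground truth.
5. `05_rlba.R` — antibody indices and positivity calls on a synthetic
   plate.

Run them in order with `Rscript analysis/01_simulate.R`, etc.
`run_pipeline()` performs the same aggregate → normalize → FC → Z →
hit-call sequence as a single call from a YAML or list config.

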