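---
title: "PhIP-seq autoantibody discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PhIP-seq autoantibody discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phipkit)
```

## The measurement and its statistical problem

Phage immunoprecipitation sequencing (PhIP-seq) displays a programmed
peptide library on phage, immunoprecipitates the phage bound by a serum
sample's antibodies, and reads out enrichment by sequencing. The raw
observation is a peptide-by-sample matrix of read counts. Three features
dominate the statistics:

1. **The background is compositional and highly skewed.** Phage
   abundances vary over orders of magnitude before any serum is added,
   and sequencing a fixed number of reads makes every column a
   composition: enriching one antigen depletes the apparent abundance of
   everything else.
2. **Every serum is autoreactive somewhere.** Healthy and disease sera
   alike strongly enrich a private set of antigens, so enrichment per se
   is not evidence of disease association; only *shared, case-specific*
   enrichment is.
3. **Bead-only (mock-IP) immunoprecipitations** measure non-specific
   phage-bead binding and define the background expectation per gene.

`phipkit` implements the post-sequencing analysis: gene-level
aggregation, normalization, fold change over mock-IP, control-referenced
Z-scores, multi-criterion hit calling, a control-downsampling
experiment, an L1-logistic disease classifier, and radioligand binding
assay (RLBA) statistics for orthogonal validation.

## Enrichment statistics

Peptide counts mapping to the same gene are summed
(`aggregate_to_gene()`). With a pseudocount of 0.5 reads added to every
gene, counts become read percentages,

$$p_{gs} = 100 \cdot \frac{c_{gs} + 0.5}{\sum_{g'} (c_{g's} + 0.5)},$$

so columns sum to exactly 100 and every entry is strictly positive. The
pseudocount is included in the denominator deliberately: it preserves
compositional closure, and the alternative (raw-total denominator)
differs only at order 0.5/depth.

Fold change divides each serum's percentage by the arithmetic mean
percentage in the mock-IP samples, gene by gene:
$\mathrm{FC}_{gs} = p_{gs} / \overline{p_{g,\mathrm{mock}}}$.

Z-scores standardize fold changes against the healthy-control cohort.
Cases are scored against all controls; each control is scored against
all *other* controls (leave-one-out), so no sample's own value inflates
its reference. The SD uses the $n-1$ denominator — the conservative
choice for the small references that arise during downsampling. When a
reference SD is exactly zero the score is defined as 0 if the value
equals the reference mean and $\pm\infty$ otherwise; infinite scores are
treated as exceeding any finite threshold downstream. This keeps the
rule monotone and reproducible. With only two controls, a leave-one-out
reference has a single member; its SD is taken as zero and the same rule
applies.

## Hit calling

A gene is a shared disease-specific hit (`call_hits()`) when, on the
chosen metric (Z-score by default):

1. at least 10% of case samples are positive (Z ≥ 10);
2. positive controls stay under the control limit — by default fewer
   than `ceiling(0.02 × n_controls)` controls; an absolute mode
   ("fewer than two controls", strict `<`) is available because both
   phrasings are in circulation for this criterion, and they differ
   once the control cohort passes 100 samples;
3. at least one positive case reaches FC ≥ 50 (a "strong" case); and
4. no control's signal exceeds the top case's signal (dominance; ties
   allowed, since a violation requires a control strictly above the
   highest case).

The default positivity inequality is ≥ (a flag switches to strict >),
and a `caption_fc10` preset judges positivity on fold change > 10
instead of Z-scores. All four diagnostics are recorded per gene whether
or not it passes.

`downsample_controls()` asks how many *apparent* hits survive as the
control cohort grows: control subsets of 5–150 are drawn without
replacement, ten times per size, and the hit criteria are re-applied.
Z-scores are recomputed against every subset — slicing the full-cohort
Z-scores would leak the held-out controls into the reference, which is
the one reading of the experiment that is not self-consistent. The
fraction-mode control limit scales with the subset size. Control
subsets are drawn once per replicate (not per gene).

`cross_cohort_overlap()` reports, for each hit in one cohort, how many
samples in a second cohort are positive for the same gene — the
operation behind asking whether two diseases share rare antigens.

## The synthetic-data generator

`simulate_dataset()` draws, from a single seeded RNG stream in
documented order:

1. gene background propensities $\lambda_g \sim \mathrm{LogNormal}(0,
   \sigma_b)$, split uniformly across each gene's peptides;
2. per-sample depths $N_s \sim \mathrm{LogNormal}(\mu_d, \sigma_d)$,
   rounded;
3. per-serum private autoreactivities (log-uniform effects) and, for
   cases, disease antigens carried with probability `penetrance` at a
   fixed multiplicative effect;
4. counts via a Dirichlet-multinomial: $\mathbf{c}_s \sim
   \mathrm{DirMult}(N_s, \kappa \cdot \tilde{\mathbf{w}}_s)$ with
   concentration $\kappa$ (`overdispersion`) scaling the normalized
   effect-weighted propensities.

The Dirichlet-multinomial was chosen over independent negative
binomials so per-sample totals are exact and compositional competition
— the hallmark of serial enrichment and amplification — is represented.
Mock-IP samples carry the background alone, making their replicates
exchangeable.

Two modeling decisions deserve emphasis:

* **Private reactivities are drawn from the non-disease genes.**
  Disease-specific antigens are, by definition, genes healthy sera
  rarely react to; a generator that sprinkled private reactivities
  uniformly over all genes would routinely place a strongly reactive
  control on a spiked antigen, and the dominance criterion would then
  (correctly) reject that antigen. The sharp split makes the spike-in
  recovery experiment a clean measure of the criteria themselves.
  Real screens live between the two regimes.
* **Scale.** The shipped `aps1_like` fixture mirrors the cohort layout
  of a large monogenic-autoimmunity screen — 128 cases, 186 healthy
  controls, 8 mock-IP — over 1000 genes × 2 peptides at ~100k reads per
  sample, with 10 antigens spiked at 100-fold effect and penetrance
  0.3, and 3 private reactivities per serum. One thousand genes keeps
  every test and the acceptance script fast while keeping the per-gene
  rate of private reactivity (3/1000) comparable to tens of private
  antigens over a proteome-scale library; depth, skew
  (`background_log_sd = 1.5`) and the concentration $\kappa = 10^4$
  (mock-replicate CVs around 30% at mid-abundance, calibrated on the
  `tiny` fixture) are realistic for enrichment sequencing. These
  parameters define the simulated study conditions and are fixed.

What the generator does **not** emulate: peptide-level epitope overlap,
PCR duplication, batch effects across runs, IVIG contamination, and
cross-reactive antigen families. Passing tests on synthetic data
therefore demonstrates the correctness and internal consistency of the
statistics, not their sensitivity or specificity on any real cohort.

## Disease classification

Features are $\log_{10}$ reads-per-100k of pseudocounted gene counts
(`build_features()`): percent × 1000, base 10. The transform uses only
per-sample totals, so it cannot leak information across samples when
applied before cross-validation splits. The classifier is L1-penalized
logistic regression (via glmnet) with the penalty parameterized as
inverse regularization strength $C$ (glmnet's $\lambda = 1/(nC)$,
default $C = 1$, no internal standardization). Evaluation uses
stratified five-fold cross-validation with a seeded fold assignment —
stratification because a 128-vs-186 imbalance makes unstratified folds
unstable — and a single ROC/AUC pooled over out-of-fold probabilities,
matching the convention of reporting one ROC curve per model.
Coefficients are reported from a full-data refit at the same penalty
and ranked by magnitude.

## RLBA statistics

The antibody index is the ratio of background-subtracted signals,
$(\text{sample} - \overline{\text{blank}}) / (\text{positive control} -
\overline{\text{blank}})$: 0 at blank level, 1 at the positive control,
negative below blank, and invariant to any common rescaling of counts.
Multiple blank or positive-control wells are averaged first. The
positivity cutoff is the healthy-control mean plus three sample SDs;
a sample exactly at the cutoff is negative (strict >). Units from the
scintillation reader are treated as opaque and assumed consistent
within a plate.

## Numerical and degenerate-input conventions

* Frequency columns sum to 100 within 1e-9 relative tolerance; the
  pipeline's core statistics are validated against brute-force loop
  implementations at that tolerance.
* Zero-SD references: see above; `call_hits()` treats $+\infty$ as
  exceeding any finite threshold.
* Zero-read samples are flagged with a warning at load, not dropped.
* Unmapped peptides abort aggregation unless dropping is requested
  explicitly, because silent loss corrupts the percentage denominator.
* Tie rules are documented where a boundary matters: positivity is ≥ by
  default, control limits are strict `<`, dominance allows ties, the
  RLBA cutoff is strict `>`.

## Problem sizes

The test suite and the acceptance script run everything at the fixture
scales above: 1000 genes × 322 samples for the cohort-level
experiments, ten replicates per control-set size in the downsampling
experiment, and 10 seeded simulations for the coefficient-recovery
property. These sizes were chosen so the full validation cycle stays
interactive while every claim is still exercised end to end.

## Known limitations

* Gene-level analysis only; peptide-level Z-scores and batch correction
  are out of scope.
* The hit criteria are thresholds, not corrected p-values — by design,
  mirroring conservative screening practice.
* Synthetic validation bounds what can be claimed about real cohorts
  (see the generator's non-goals above).
* Each peptide maps to exactly one gene; isoform ambiguity must be
  resolved upstream.
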