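# Memoized fixtures so expensive datasets are built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name) {
  if (!exists(name, envir = .fixture_cache)) {
    ds <- make_fixture(name)
    ds$gene <- aggregate_to_gene(ds$counts, ds$map)
    ds$freq <- normalize_counts(ds$gene)
    ds$fc <- fold_change(ds$freq, ds$sheet)
    ds$z <- zscore(ds$fc, ds$sheet)
    assign(name, ds, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small random gene-level dataset with a sheet, for oracle comparisons.
random_gene_dataset <- function(n_genes = 30, n_cases = 10, n_controls = 25,
                                n_mock = 5, seed = 1) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(n_genes))
  samples <- c(sprintf("ca%02d", seq_len(n_cases)),
               sprintf("co%02d", seq_len(n_controls)),
               sprintf("mk%02d", seq_len(n_mock)))
  counts <- matrix(rnbinom(n_genes * length(samples), mu = 50, size = 0.5),
                   nrow = n_genes, dimnames = list(ids, samples))
  sheet <- data.frame(sample_id = samples,
                      role = rep(c("case", "control", "mock_ip"),
                                 c(n_cases, n_controls, n_mock)),
                      cohort = "rand", stringsAsFactors = FALSE)
  list(gene = count_matrix(counts, "gene"), sheet = sheet)
}
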