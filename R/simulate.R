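#' Simulation configuration for synthetic PhIP-seq datasets
#'
#' Defines the generative model for seeded synthetic datasets with the
#' statistical structure of a PhIP-seq screen: a highly skewed phage
#' library background shared by all immunoprecipitations, mock-IP
#' (bead-only) replicates sampling that background alone, per-serum
#' "private" autoreactivities present regardless of disease status, and
#' disease-specific antigens carried by a configurable fraction of cases
#' at large multiplicative enrichments.
#'
#' @param n_genes Number of genes in the library.
#' @param peptides_per_gene Peptides tiled per gene (scalar).
#' @param n_cases,n_controls,n_mock Cohort sizes; mock-IP are bead-only.
#' @param depth_log_mean,depth_log_sd Log-normal parameters of per-sample
#'   library size (total reads).
#' @param background_log_sd Log-normal spread of gene bead-binding
#'   propensities (the skew of the background).
#' @param n_private Private autoreactive genes per serum (case or
#'   control), drawn without replacement from the non-disease genes.
#' @param private_effect_range Length-2 numeric `(lo, hi)`; private
#'   enrichment effects are drawn log-uniformly on this range.
#' @param disease_genes Character vector of spiked disease antigens
#'   (must be a subset of the simulated gene set).
#' @param penetrance Probability a case carries each disease antigen.
#' @param disease_effect Multiplicative enrichment for carried antigens.
#' @param overdispersion Dirichlet concentration scaling; larger values
#'   approach multinomial sampling of the expected composition.
#' @param seed Integer seed; identical configs and seeds give
#'   bit-identical datasets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100, peptides_per_gene = 2,
                       n_cases = 10, n_controls = 10, n_mock = 4,
                       depth_log_mean = log(1e5), depth_log_sd = 0.3,
                       background_log_sd = 1.5,
                       n_private = 3, private_effect_range = c(10, 100),
                       disease_genes = character(0),
                       penetrance = 0, disease_effect = 1,
                       overdispersion = 1e4, seed = 1L) {
  cfg <- list(n_genes = n_genes, peptides_per_gene = peptides_per_gene,
              n_cases = n_cases, n_controls = n_controls, n_mock = n_mock,
              depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
              background_log_sd = background_log_sd,
              n_private = n_private, private_effect_range = private_effect_range,
              disease_genes = disease_genes, penetrance = penetrance,
              disease_effect = disease_effect, overdispersion = overdispersion,
              seed = as.integer(seed))
  if (penetrance < 0 || penetrance > 1) stop("penetrance must be in [0, 1]")
  if (disease_effect < 1 || any(private_effect_range < 1)) stop("effects must be >= 1")
  if (overdispersion <= 0) stop("overdispersion must be > 0")
  if (n_private > n_genes) stop("n_private exceeds n_genes")
  class(cfg) <- "sim_config"
  cfg
}

gene_ids_for <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate a PhIP-seq dataset with spike-in ground truth
#'
#' Generative model, draws consumed in this order from a single seeded
#' RNG stream: (1) gene background propensities lambda_g ~
#' LogNormal(0, background_log_sd), split uniformly across each gene's
#' peptides; (2) per-sample depths N_s ~ LogNormal(depth_log_mean,
#' depth_log_sd) rounded to integer; (3) for each serum (cases then
#' controls), private genes drawn without replacement from the
#' non-disease genes with log-uniform effects, and for cases each
#' disease gene carried with probability `penetrance` at effect
#' `disease_effect`; (4) per sample, peptide counts drawn
#' Dirichlet-multinomial(N_s, overdispersion x normalized propensities).
#' Mock-IP samples carry the background only.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `counts` (peptide-level count matrix),
#'   `map` (peptide-to-gene data.frame), `sheet` (sample sheet), and
#'   `truth` (data.frame sample_id/gene_id/effect/origin plus the config
#'   as attribute `config`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$disease_genes) == 0 && cfg$penetrance > 0)
    warning("penetrance > 0 with no disease genes: no disease signal simulated")
  genes <- gene_ids_for(cfg$n_genes)
  if (!all(cfg$disease_genes %in% genes))
    stop("disease_genes outside the simulated gene set")
  ppg <- cfg$peptides_per_gene
  pep_gene <- rep(genes, each = ppg)
  pep_ids <- paste0(pep_gene, "_p", rep(seq_len(ppg), times = cfg$n_genes))

  sample_ids <- c(sprintf("case_%03d", seq_len(cfg$n_cases)),
                  sprintf("ctrl_%03d", seq_len(cfg$n_controls)),
                  sprintf("mock_%02d", seq_len(cfg$n_mock)))
  roles <- rep(c("case", "control", "mock_ip"),
               c(cfg$n_cases, cfg$n_controls, cfg$n_mock))

  old <- .Random.seed_exists()
  set.seed(cfg$seed)
  lambda <- stats::rlnorm(cfg$n_genes, 0, cfg$background_log_sd)
  depths <- pmax(1L, as.integer(round(stats::rlnorm(length(sample_ids),
                                                    cfg$depth_log_mean,
                                                    cfg$depth_log_sd))))
  private_pool <- setdiff(genes, cfg$disease_genes)
  truth <- list()
  effect_mat <- matrix(1, nrow = cfg$n_genes, ncol = length(sample_ids),
                       dimnames = list(genes, sample_ids))
  for (j in seq_along(sample_ids)) {
    if (roles[j] == "mock_ip") next
    priv <- sample(private_pool, min(cfg$n_private, length(private_pool)))
    lo <- log(cfg$private_effect_range[1]); hi <- log(cfg$private_effect_range[2])
    eff <- exp(stats::runif(length(priv), lo, hi))
    effect_mat[priv, j] <- effect_mat[priv, j] * eff
    if (length(priv))
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = sample_ids[j], gene_id = priv, effect = eff,
        origin = "private", stringsAsFactors = FALSE)
    if (roles[j] == "case" && length(cfg$disease_genes)) {
      carried <- cfg$disease_genes[stats::runif(length(cfg$disease_genes)) < cfg$penetrance]
      if (length(carried)) {
        effect_mat[carried, j] <- effect_mat[carried, j] * cfg$disease_effect
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = sample_ids[j], gene_id = carried,
          effect = cfg$disease_effect, origin = "disease",
          stringsAsFactors = FALSE)
      }
    }
  }

  pep_lambda <- lambda[match(pep_gene, genes)] / ppg
  counts <- matrix(0L, nrow = length(pep_ids), ncol = length(sample_ids),
                   dimnames = list(pep_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    w <- pep_lambda * effect_mat[match(pep_gene, genes), j]
    alpha <- cfg$overdispersion * w / sum(w)
    p <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    p <- p / sum(p)
    counts[, j] <- as.integer(stats::rmultinom(1, depths[j], p))
  }
  .Random.seed_restore(old)

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample_id = character(0), gene_id = character(0),
               effect = numeric(0), origin = character(0))
  attr(truth_df, "config") <- cfg
  sheet <- data.frame(sample_id = sample_ids, role = roles,
                      cohort = "sim", stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, "peptide"),
       map = data.frame(peptide_id = pep_ids, gene_id = pep_gene,
                        stringsAsFactors = FALSE),
       sheet = sheet, truth = truth_df)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Named fixture datasets
#'
#' Seeded presets used throughout the test suite and the analysis
#' scripts:
#' \describe{
#'   \item{tiny}{8 genes x 2 peptides, 2 cases / 2 controls / 2 mock;
#'     hand-checkable.}
#'   \item{aps1_like}{128 cases / 186 controls / 8 mock-IP over 1000
#'     genes, mirroring the APS1 cohort layout; 10 disease antigens
#'     spiked at 100-fold enrichment with penetrance 0.3.}
#'   \item{null}{As `aps1_like` but with no disease genes.}
#' }
#'
#' @param name One of `"tiny"`, `"aps1_like"`, `"null"`.
#' @param seed Optional seed override (default: the preset's fixed seed).
#' @return As [simulate_dataset()].
#' @export
make_fixture <- function(name = c("tiny", "aps1_like", "null"), seed = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = sim_config(n_genes = 8, peptides_per_gene = 2,
                      n_cases = 2, n_controls = 2, n_mock = 2,
                      depth_log_mean = log(2e4), depth_log_sd = 0.2,
                      n_private = 1, private_effect_range = c(10, 20),
                      seed = 101L),
    aps1_like = sim_config(n_genes = 1000, peptides_per_gene = 2,
                           n_cases = 128, n_controls = 186, n_mock = 8,
                           depth_log_mean = log(1e5), depth_log_sd = 0.3,
                           n_private = 3, private_effect_range = c(10, 100),
                           disease_genes = gene_ids_for(1000)[1:10],
                           penetrance = 0.3, disease_effect = 100,
                           seed = 2021L),
    null = sim_config(n_genes = 1000, peptides_per_gene = 2,
                      n_cases = 128, n_controls = 186, n_mock = 8,
                      depth_log_mean = log(1e5), depth_log_sd = 0.3,
                      n_private = 3, private_effect_range = c(10, 100),
                      seed = 2022L))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  simulate_dataset(cfg)
}
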