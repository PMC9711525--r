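#' Normalize gene counts to pseudocounted read percentages
#'
#' Adds a pseudocount of 0.5 reads to every gene, then converts each
#' sample to percentage of total (pseudocounted) reads, so every entry is
#' strictly positive and each column sums to exactly 100.
#'
#' @param gene_counts Gene-level count matrix.
#' @param pseudocount Reads added to every gene (default 0.5).
#' @return Numeric matrix of percentages, genes x samples.
#' @export
normalize_counts <- function(gene_counts, pseudocount = 0.5) {
  if (length(gene_counts) == 0) stop("empty count matrix")
  x <- gene_counts + pseudocount
  100 * sweep(x, 2, colSums(x), "/")
}

#' Fold change over mock-IP background
#'
#' For every gene, divides each serum sample's read percentage by the
#' arithmetic mean read percentage across the mock-IP (bead-only)
#' samples. Mock-IP columns are excluded from the result. The pseudocount
#' in [normalize_counts()] keeps the denominator positive.
#'
#' @param freq Percentage matrix from [normalize_counts()].
#' @param sheet Sample sheet with a `role` column; `mock_ip` rows define
#'   the background.
#' @return Fold-change matrix, genes x non-mock samples.
#' @export
fold_change <- function(freq, sheet) {
  sheet <- validate_sample_sheet(sheet)
  mock <- intersect(samples_with_role(sheet, "mock_ip"), colnames(freq))
  if (length(mock) == 0) stop("no mock_ip samples available for fold change")
  serum <- setdiff(colnames(freq), mock)
  mock_mean <- rowMeans(freq[, mock, drop = FALSE])
  freq[, serum, drop = FALSE] / mock_mean
}

row_mean_sd <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  s <- if (n >= 2) sqrt(pmax(0, (rowSums(x^2) - n * m^2) / (n - 1))) else rep(0, nrow(x))
  list(mean = m, sd = s)
}

zero_sd_z <- function(value, mu) ifelse(value == mu, 0, sign(value - mu) * Inf)

#' Control-referenced Z-scores of fold changes
#'
#' Standardizes each sample's fold change per gene against the healthy
#' control cohort: disease (case) samples are scored against all
#' controls; each control is scored leave-one-out against all other
#' controls, so no control's own value enters its reference. The SD uses
#' the n-1 (sample) denominator. Where a reference SD is zero the score
#' is 0 if the value equals the reference mean and +/-Inf otherwise
#' (flagged, and treated as exceeding any finite threshold downstream).
#' Mock-IP samples never receive Z-scores.
#'
#' @param fc Fold-change matrix from [fold_change()].
#' @param sheet Sample sheet; `control` rows define the reference.
#' @param control_ids Optional explicit control set (defaults to all
#'   `control`-role samples present in `fc`), e.g. for scoring a cohort
#'   against non-disease controls of another cohort.
#' @return Z-score matrix over the case and control columns of `fc`.
#' @export
zscore <- function(fc, sheet, control_ids = NULL) {
  sheet <- validate_sample_sheet(sheet)
  if (is.null(control_ids))
    control_ids <- samples_with_role(sheet, "control")
  ctrl <- intersect(control_ids, colnames(fc))
  if (length(ctrl) < 2) stop("need >= 2 control samples for Z-scores")
  cases <- intersect(samples_with_role(sheet, "case"), colnames(fc))
  fc_c <- fc[, ctrl, drop = FALSE]
  n <- length(ctrl)
  ref <- row_mean_sd(fc_c)
  z <- matrix(NA_real_, nrow = nrow(fc), ncol = length(cases) + n,
              dimnames = list(rownames(fc), c(cases, ctrl)))
  for (s in cases) {
    zs <- (fc[, s] - ref$mean) / ref$sd
    deg <- ref$sd == 0
    if (any(deg)) zs[deg] <- zero_sd_z(fc[deg, s], ref$mean[deg])
    z[, s] <- zs
  }
  # leave-one-out moments from cohort sums: mean_{-c} = (S - x_c)/(n-1),
  # var_{-c} = (SS - x_c^2 - (n-1) mean_{-c}^2)/(n-2)
  S <- rowSums(fc_c)
  SS <- rowSums(fc_c^2)
  for (c_id in ctrl) {
    x <- fc_c[, c_id]
    m_loo <- (S - x) / (n - 1)
    s_loo <- if (n >= 3) sqrt(pmax(0, (SS - x^2 - (n - 1) * m_loo^2) / (n - 2))) else rep(0, nrow(fc))
    zs <- (x - m_loo) / s_loo
    deg <- s_loo == 0
    if (any(deg)) zs[deg] <- zero_sd_z(x[deg], m_loo[deg])
    z[, c_id] <- zs
  }
  z
}

#' Per-sample enrichment profile
#'
#' Counts, for each sample, how many genes reach each fold-change
#' threshold (default 5, 10, 25, 50, 100-fold over mock-IP). Counts are
#' non-increasing in the threshold.
#'
#' @param fc Fold-change matrix.
#' @param thresholds Positive fold-change thresholds.
#' @return data.frame with `sample_id` and one `fc_ge_<t>` column per
#'   threshold.
#' @export
enrichment_profile <- function(fc, thresholds = c(5, 10, 25, 50, 100)) {
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  hits <- vapply(thresholds, function(t) colSums(fc >= t),
                 numeric(ncol(fc)))
  hits <- matrix(hits, ncol = length(thresholds),
                 dimnames = list(colnames(fc), paste0("fc_ge_", thresholds)))
  data.frame(sample_id = colnames(fc), hits, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}
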