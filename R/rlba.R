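#' Radioligand binding assay antibody index
#'
#' Index = (sample - mean blank) / (positive control - mean blank) on
#' scintillation counts. Multiple blank and positive-control wells are
#' averaged arithmetically before use. The index is invariant to a
#' common rescaling of all counts and may be negative when the sample
#' falls below the blank mean.
#'
#' @param sample_cpm Numeric vector of sample well counts.
#' @param blank_cpms Numeric vector of blank well counts.
#' @param positive_cpm Numeric vector of positive-control well counts.
#' @return Numeric vector of antibody indices.
#' @export
antibody_index <- function(sample_cpm, blank_cpms, positive_cpm) {
  if (any(c(sample_cpm, blank_cpms, positive_cpm) < 0)) stop("cpm must be >= 0")
  blank <- mean(blank_cpms)
  pos <- mean(positive_cpm)
  if (pos <= blank) stop("positive control does not exceed blank mean: assay failure")
  (sample_cpm - blank) / (pos - blank)
}

#' Antibody indices from a plate table
#'
#' @param plate data.frame with columns `role` (one of `sample`,
#'   `blank`, `positive_control`, `healthy_control`), `sample_id`, and
#'   `cpm`. Healthy-control wells are indexed like samples and used by
#'   [call_positives()] for the cutoff.
#' @return data.frame `sample_id`, `role`, `index` for sample and
#'   healthy-control wells.
#' @export
rlba_indices <- function(plate) {
  need <- c("role", "sample_id", "cpm")
  if (!all(need %in% colnames(plate))) stop("plate needs columns role, sample_id, cpm")
  plate$cpm <- as.numeric(plate$cpm)
  blanks <- plate$cpm[plate$role == "blank"]
  pos <- plate$cpm[plate$role == "positive_control"]
  if (length(blanks) < 1 || length(pos) < 1)
    stop("plate needs >= 1 blank and >= 1 positive_control well")
  idx <- plate$role %in% c("sample", "healthy_control")
  data.frame(sample_id = plate$sample_id[idx], role = plate$role[idx],
             index = antibody_index(plate$cpm[idx], blanks, pos),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call antibody-positive samples from indices
#'
#' Positivity cutoff = mean of healthy-control indices + 3 sample SDs
#' (n-1 denominator); a sample is positive when its index strictly
#' exceeds the cutoff (a tie is negative).
#'
#' @param indices Named numeric vector of antibody indices, or the
#'   data.frame from [rlba_indices()].
#' @param healthy_ids Sample ids forming the healthy reference (default:
#'   `healthy_control` rows when `indices` is a data.frame).
#' @return data.frame `sample_id`, `index`, `cutoff`, `positive`.
#' @export
call_positives <- function(indices, healthy_ids = NULL) {
  if (is.data.frame(indices)) {
    if (is.null(healthy_ids))
      healthy_ids <- indices$sample_id[indices$role == "healthy_control"]
    indices <- stats::setNames(indices$index, indices$sample_id)
  }
  healthy <- indices[names(indices) %in% healthy_ids]
  if (length(healthy) < 2) stop("need >= 2 healthy controls for the SD cutoff")
  cutoff <- mean(healthy) + 3 * stats::sd(healthy)
  data.frame(sample_id = names(indices), index = as.numeric(indices),
             cutoff = cutoff, positive = as.numeric(indices) > cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}
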