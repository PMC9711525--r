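#' Read a PhIP-seq count matrix from delimited text
#'
#' Reads a features-by-samples table of nonnegative integer read counts.
#' The first column holds feature identifiers (peptide or gene ids,
#' case-sensitive opaque strings); every remaining column is one sample.
#' Tab-separated files are canonical; comma-separated files are accepted.
#' A header row is mandatory. Input feature and sample order is preserved.
#'
#' @param path Path to a TSV or CSV file.
#' @param level Either `"peptide"` or `"gene"`; recorded on the result.
#' @return An integer matrix (features x samples) with rownames = feature
#'   ids, colnames = sample ids, and attribute `level`.
#' @export
read_count_matrix <- function(path, level = c("peptide", "gene")) {
  level <- match.arg(level)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count file must have a feature-id column and >=1 sample column: ", path)
  feature_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) stop("duplicated sample ids in header: ", paste(dup_s, collapse = ", "))
  dup_f <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup_f)) stop("duplicated feature ids: ", paste(dup_f, collapse = ", "))
  num <- suppressWarnings(vapply(df[-1], as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df), dimnames = list(feature_ids, sample_ids))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-count cell(s): %s",
                 paste(sprintf("row '%s' / column '%s'",
                               feature_ids[bad[, 1]], sample_ids[bad[, 2]])[seq_len(min(5, nrow(bad)))],
                       collapse = "; ")))
  }
  counts <- matrix(as.integer(num), nrow = nrow(num), dimnames = dimnames(num))
  count_matrix(counts, level = level)
}

#' Construct and validate a count matrix
#'
#' @param counts Integer matrix, features x samples, with dimnames.
#' @param level `"peptide"` or `"gene"`.
#' @return The validated matrix with attribute `level`. Samples with zero
#'   total reads are flagged with a warning (not an error).
#' @export
count_matrix <- function(counts, level = c("peptide", "gene")) {
  level <- match.arg(level)
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must be a matrix with feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicated feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  empty <- colSums(counts) == 0
  if (any(empty))
    warning("sample(s) with zero total reads: ", paste(colnames(counts)[empty], collapse = ", "))
  attr(counts, "level") <- level
  counts
}

#' Write a count matrix as TSV
#'
#' First column `feature_id`, then one column per sample; round-trips
#' losslessly through [read_count_matrix()].
#'
#' @param counts Matrix from [count_matrix()] or [read_count_matrix()].
#' @param path Output path.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peptide-to-gene map
#'
#' Two-column TSV (`peptide_id`, `gene_id`); each peptide maps to exactly
#' one gene.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `peptide_id`, `gene_id`.
#' @export
read_peptide_gene_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("peptide_id", "gene_id") %in% colnames(df)))
    stop("peptide map needs columns peptide_id, gene_id")
  if (anyDuplicated(df$peptide_id))
    stop("peptide(s) mapped more than once: ",
         paste(unique(df$peptide_id[duplicated(df$peptide_id)]), collapse = ", "))
  df[, c("peptide_id", "gene_id")]
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id`, `role`, `cohort` plus free metadata
#' columns. Roles must be `case`, `control`, or `mock_ip`.
#'
#' @param path Path to the CSV.
#' @return data.frame; validated by [validate_sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample sheet data.frame
#'
#' @param sheet data.frame with at least `sample_id` and `role`.
#' @return The sheet, invisibly validated (returned visibly).
#' @export
validate_sample_sheet <- function(sheet) {
  if (!all(c("sample_id", "role") %in% colnames(sheet)))
    stop("sample sheet needs columns sample_id, role")
  if (anyDuplicated(sheet$sample_id)) stop("duplicated sample ids in sheet")
  bad <- setdiff(unique(sheet$role), c("case", "control", "mock_ip"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (is.null(sheet$cohort)) sheet$cohort <- "default"
  sheet
}

samples_with_role <- function(sheet, role) sheet$sample_id[sheet$role == role]

#' Aggregate peptide-level counts to gene level
#'
#' Gene counts are the exact integer sum of the gene's peptide counts in
#' each sample; per-sample totals are conserved when no peptides are
#' dropped. Peptides absent from the map are an error unless
#' `drop_unmapped = TRUE`, in which case they are discarded with a message
#' reporting how many.
#'
#' @param pep Peptide-level count matrix.
#' @param map data.frame from [read_peptide_gene_map()].
#' @param drop_unmapped Discard unmapped peptides instead of erroring.
#' @return Gene-level count matrix (attribute `level = "gene"`), genes in
#'   first-appearance order of the map restricted to peptides present.
#' @export
aggregate_to_gene <- function(pep, map, drop_unmapped = FALSE) {
  if (!identical(attr(pep, "level"), "peptide"))
    stop("aggregate_to_gene expects a peptide-level matrix")
  unmapped <- setdiff(rownames(pep), map$peptide_id)
  if (length(unmapped)) {
    if (!drop_unmapped)
      stop("unmapped peptide(s): ", paste(utils::head(unmapped, 10), collapse = ", "),
           if (length(unmapped) > 10) sprintf(" ... (%d total)", length(unmapped)) else "")
    message(length(unmapped), " unmapped peptide(s) dropped")
    pep <- pep[setdiff(rownames(pep), unmapped), , drop = FALSE]
  }
  gene_of <- stats::setNames(map$gene_id, map$peptide_id)[rownames(pep)]
  genes <- unique(gene_of)
  out <- rowsum(pep + 0L, group = factor(gene_of, levels = genes), reorder = FALSE)
  out <- matrix(as.integer(out), nrow = nrow(out),
                dimnames = list(genes, colnames(pep)))
  count_matrix(out, level = "gene")
}
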