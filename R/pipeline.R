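#' Run the full PhIP-seq analysis pipeline
#'
#' Orchestrates aggregate -> normalize -> fold change -> Z-score -> hit
#' calling over one dataset, optionally followed by the
#' control-downsampling experiment and the disease classifier. All
#' intermediate matrices are written as TSV under `out_dir` together
#' with a JSON manifest (config echo, seed, per-stage dimensions).
#' Identical config and seed give byte-identical outputs.
#'
#' @param config Either a list or a path to a YAML file with elements:
#'   `counts`, `map`, `sheet` (paths) or `dataset` (an in-memory list as
#'   returned by [simulate_dataset()]); optional `criteria` (arguments
#'   to [hit_criteria()]), `downsample` (logical or a list with `sizes`
#'   and `reps`), `classify` (logical), `drop_unmapped`, `seed`,
#'   `out_dir`.
#' @param out_dir Output directory (overrides the config entry).
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir)) stop("out_dir required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(config$dataset)) {
    ds <- config$dataset
  } else {
    ds <- stage("load", list(
      counts = read_count_matrix(config$counts, "peptide"),
      map = read_peptide_gene_map(config$map),
      sheet = read_sample_sheet(config$sheet)))
  }
  drop_unmapped <- isTRUE(config$drop_unmapped)
  gene <- stage("aggregate", aggregate_to_gene(ds$counts, ds$map, drop_unmapped))
  freq <- stage("normalize", normalize_counts(gene))
  fc <- stage("fold_change", fold_change(freq, ds$sheet))
  z <- stage("zscore", zscore(fc, ds$sheet))
  crit <- do.call(hit_criteria, as.list(config$criteria))
  hits <- stage("call_hits", call_hits(z, fc, ds$sheet, crit))

  write_mat <- function(m, name) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_count_matrix(gene, file.path(config$out_dir, "gene_counts.tsv"))
  write_mat(freq, "read_percent.tsv")
  write_mat(fc, "fold_change.tsv")
  write_mat(z, "zscore.tsv")
  utils::write.table(hits, file.path(config$out_dir, "hit_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("phipkit")),
    seed = seed,
    criteria = unclass(crit)[!vapply(unclass(crit), is.null, logical(1))],
    stages = list(
      aggregate = dim(gene), normalize = dim(freq),
      fold_change = dim(fc), zscore = dim(z),
      call_hits = c(nrow(hits), sum(hits$passed))),
    outputs = c("gene_counts.tsv", "read_percent.tsv", "fold_change.tsv",
                "zscore.tsv", "hit_table.tsv"))

  if (!is.null(config$downsample) && !isFALSE(config$downsample)) {
    dsc <- if (is.list(config$downsample)) config$downsample else list()
    sizes <- if (is.null(dsc$sizes)) c(5, 10, 25, 50, 100, 150) else dsc$sizes
    reps <- if (is.null(dsc$reps)) 10 else dsc$reps
    curve <- stage("downsample",
                   downsample_controls(fc, ds$sheet, crit, sizes, reps, seed))
    utils::write.table(curve$summary, file.path(config$out_dir, "downsampling.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$downsample <- nrow(curve$per_rep)
    manifest$outputs <- c(manifest$outputs, "downsampling.tsv")
    manifest$downsampling <- curve$summary
  }
  if (isTRUE(config$classify)) {
    fm <- stage("classify_features", build_features(gene, ds$sheet))
    cv <- stage("classify", fit_evaluate(fm, seed = seed))
    coefs <- data.frame(gene_id = names(cv$coefficients),
                        coefficient = as.numeric(cv$coefficients))
    coefs <- coefs[order(-abs(coefs$coefficient), coefs$gene_id), ]
    utils::write.table(coefs, file.path(config$out_dir, "classifier_coefficients.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    scores <- data.frame(sample_id = names(cv$oof_prob),
                         oof_probability = as.numeric(cv$oof_prob),
                         fold = cv$fold[names(cv$oof_prob)])
    utils::write.table(scores, file.path(config$out_dir, "classifier_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$auc <- cv$auc
    manifest$outputs <- c(manifest$outputs,
                          "classifier_coefficients.tsv", "classifier_scores.tsv")
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Human-readable run summary
#'
#' Renders the manifest of a completed [run_pipeline()] run as a short
#' markdown summary: passing genes (sorted by the number of positive
#' cases, then id), the downsampling table, and the AUC when present.
#' Regeneration is idempotent. Missing stage outputs produce a partial
#' report with warnings.
#'
#' @param out_dir The pipeline output directory.
#' @param path Optional file to write the summary to.
#' @return Character vector of summary lines, invisibly when `path`
#'   given.
#' @export
report_summary <- function(out_dir, path = NULL) {
  mf <- file.path(out_dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", out_dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  lines <- c("# PhIP-seq run summary", "",
             paste0("seed: ", manifest$seed))
  ht_path <- file.path(out_dir, "hit_table.tsv")
  if (file.exists(ht_path)) {
    ht <- utils::read.delim(ht_path, stringsAsFactors = FALSE)
    passed <- ht[ht$passed, , drop = FALSE]
    passed <- passed[order(-passed$n_cases_positive, passed$gene_id), , drop = FALSE]
    lines <- c(lines, "", sprintf("%d genes passed the hit criteria", nrow(passed)))
    if (nrow(passed))
      lines <- c(lines, paste0("- ", passed$gene_id, " (", passed$n_cases_positive,
                               " positive cases)"))
  } else {
    warning("hit_table.tsv missing; partial report")
    lines <- c(lines, "", "hit table missing")
  }
  ds_path <- file.path(out_dir, "downsampling.tsv")
  if (file.exists(ds_path)) {
    ds <- utils::read.delim(ds_path)
    lines <- c(lines, "", "## Apparent hits by control-set size",
               sprintf("- n = %d: mean %.1f (sd %.1f)", ds$size, ds$mean_hits, ds$sd_hits))
  }
  if (!is.null(manifest$auc))
    lines <- c(lines, "", sprintf("classifier AUC: %.3f", manifest$auc))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
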