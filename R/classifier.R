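#' Log-scaled feature matrix for disease classification
#'
#' Transforms gene counts to log10 reads-per-100k with the same 0.5
#' pseudocount used throughout: x[g,s] = log10(1e5 * (count + 0.5) /
#' column pseudocounted total). Only per-sample totals enter the
#' transform, so it can be applied before any train/test split without
#' leaking information across samples. Mock-IP samples are excluded.
#'
#' @param gene_counts Gene-level count matrix.
#' @param sheet Sample sheet (cases and controls kept).
#' @param scale Reads scale (default 1e5, i.e. reads per 100k).
#' @param pseudocount Pseudocount (default 0.5).
#' @param base Logarithm base (default 10).
#' @return Numeric matrix genes x samples with attribute
#'   `transform_spec` recording all three choices, and `labels` (named
#'   0/1 vector, 1 = case).
#' @export
build_features <- function(gene_counts, sheet, scale = 1e5,
                           pseudocount = 0.5, base = 10) {
  sheet <- validate_sample_sheet(sheet)
  keep <- sheet$sample_id[sheet$role %in% c("case", "control")]
  keep <- intersect(colnames(gene_counts), keep)
  roles <- stats::setNames(sheet$role, sheet$sample_id)[keep]
  if (!any(roles == "case") || !any(roles == "control"))
    stop("need both case and control samples to build features")
  x <- gene_counts[, keep, drop = FALSE] + pseudocount
  x <- log(scale * sweep(x, 2, colSums(x), "/"), base = base)
  attr(x, "transform_spec") <- list(scale = scale, pseudocount = pseudocount, base = base)
  attr(x, "labels") <- stats::setNames(as.integer(roles == "case"), keep)
  x
}

stratified_folds <- function(labels, folds, seed) {
  if (min(table(labels)) < folds)
    stop("need at least `folds` samples per class for stratified folds")
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  assign_class <- function(idx) {
    k <- sample(rep_len(seq_len(folds), length(idx)))
    stats::setNames(k, names(idx))
  }
  fold <- integer(length(labels))
  names(fold) <- names(labels)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- assign_class(idx)
  }
  .Random.seed_restore(old)
  fold
}

#' Fit and evaluate an L1-penalized logistic-regression classifier
#'
#' Stratified k-fold cross-validation (seeded): the model is refit on
#' each training split, out-of-fold predicted probabilities are pooled
#' into a single ROC curve and AUC, and final coefficients come from a
#' full-data fit at the same penalty. The penalty follows the
#' inverse-regularization convention: the glmnet lambda is
#' 1 / (n_train * l1_strength).
#'
#' @param fm Feature matrix from [build_features()] (genes x samples,
#'   with the `labels` attribute), or any numeric matrix plus `labels`.
#' @param labels Optional named 0/1 vector overriding the attribute.
#' @param folds Number of cross-validation folds (default 5).
#' @param l1_strength Inverse regularization strength C (default 1).
#' @param seed Seed for the fold assignment.
#' @return List of class `phip_cv`: `auc`, `roc` (a pROC object),
#'   `oof_prob` (pooled out-of-fold probabilities), `fold` assignments,
#'   `coefficients` (named vector from the full-data fit, no intercept),
#'   `ranking` (genes by decreasing |coefficient|), `l1_strength`.
#' @export
fit_evaluate <- function(fm, labels = NULL, folds = 5, l1_strength = 1,
                         seed = 1L) {
  if (is.null(labels)) labels <- attr(fm, "labels")
  if (is.null(labels)) stop("labels required")
  labels <- labels[colnames(fm)]
  X <- t(fm)                                   # samples x genes for glmnet
  fold <- stratified_folds(labels, folds, seed)
  oof <- rep(NA_real_, length(labels))
  names(oof) <- names(labels)
  for (k in seq_len(folds)) {
    tr <- fold != k
    lam <- 1 / (sum(tr) * l1_strength)
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], labels[tr],
                          family = "binomial", alpha = 1,
                          lambda = lam, standardize = FALSE)
    oof[!tr] <- as.numeric(stats::predict(fit, X[!tr, , drop = FALSE],
                                          type = "response"))
  }
  roc <- pROC::roc(response = labels, predictor = oof, quiet = TRUE,
                   direction = "<", levels = c(0, 1))
  lam_full <- 1 / (nrow(X) * l1_strength)
  full <- glmnet::glmnet(X, labels, family = "binomial", alpha = 1,
                         lambda = lam_full, standardize = FALSE)
  coefs <- as.numeric(stats::coef(full))[-1]
  names(coefs) <- rownames(fm)
  structure(list(auc = as.numeric(pROC::auc(roc)), roc = roc,
                 oof_prob = oof, fold = fold, coefficients = coefs,
                 ranking = names(sort(abs(coefs), decreasing = TRUE)),
                 l1_strength = l1_strength, seed = as.integer(seed)),
            class = "phip_cv")
}
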