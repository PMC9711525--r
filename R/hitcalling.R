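#' Criteria for calling shared disease-specific hits
#'
#' A gene is a shared hit when all of the following hold on the chosen
#' metric (Z-score by default):
#' (1) at least `case_min_frac` of case samples are positive
#'     (metric >= `positive_threshold`, or > with `strict_inequality`);
#' (2) positive controls stay below the control limit — either fewer
#'     than `ceiling(control_max_frac * n_controls)` controls (fraction
#'     mode, default 2\%) or strictly fewer than `control_max_count`
#'     controls (absolute mode, e.g. "less than two");
#' (3) at least one positive case reaches fold change
#'     >= `strong_fc_min`;
#' (4) with `dominance_rule`, no control's signal exceeds the highest
#'     case signal (ties allowed).
#' Exactly one of `control_max_frac` / `control_max_count` may be set.
#'
#' @param metric `"zscore"` or `"fold_change"`: the matrix positivity is
#'   judged on.
#' @param positive_threshold Positivity threshold on the metric.
#' @param case_min_frac Minimum fraction of positive cases.
#' @param control_max_frac Fraction mode limit on positive controls.
#' @param control_max_count Absolute mode limit (strict `<`).
#' @param strong_fc_min Minimum fold change required of at least one
#'   positive case.
#' @param dominance_rule Apply criterion (4).
#' @param strict_inequality Use `>` instead of `>=` for positivity.
#' @return List of class `hit_criteria`.
#' @export
hit_criteria <- function(metric = c("zscore", "fold_change"),
                         positive_threshold = 10,
                         case_min_frac = 0.10,
                         control_max_frac = 0.02,
                         control_max_count = NULL,
                         strong_fc_min = 50,
                         dominance_rule = TRUE,
                         strict_inequality = FALSE) {
  metric <- match.arg(metric)
  if (!is.null(control_max_frac) && !is.null(control_max_count))
    stop("set exactly one of control_max_frac / control_max_count")
  if (is.null(control_max_frac) && is.null(control_max_count))
    stop("set exactly one of control_max_frac / control_max_count")
  if (positive_threshold <= 0 || strong_fc_min <= 0) stop("thresholds must be > 0")
  if (case_min_frac <= 0 || case_min_frac > 1) stop("case_min_frac must be in (0, 1]")
  structure(list(metric = metric, positive_threshold = positive_threshold,
                 case_min_frac = case_min_frac,
                 control_max_frac = control_max_frac,
                 control_max_count = control_max_count,
                 strong_fc_min = strong_fc_min,
                 dominance_rule = dominance_rule,
                 strict_inequality = strict_inequality),
            class = "hit_criteria")
}

#' Named criteria presets
#'
#' `"default"` is the Z-score >= 10 criteria set of [hit_criteria()];
#' `"results_text"` uses strict Z > 10 with the absolute "fewer than two
#' controls" limit; `"caption_fc10"` judges positivity on fold change
#' > 10 over mock-IP.
#'
#' @param name Preset name.
#' @return A `hit_criteria` object.
#' @export
hit_criteria_preset <- function(name = c("default", "results_text", "caption_fc10")) {
  name <- match.arg(name)
  switch(name,
    default = hit_criteria(),
    results_text = hit_criteria(positive_threshold = 10, strict_inequality = TRUE,
                                control_max_frac = NULL, control_max_count = 2),
    caption_fc10 = hit_criteria(metric = "fold_change", positive_threshold = 10,
                                strict_inequality = TRUE))
}

#' Call shared disease-specific hits
#'
#' Applies the four criteria of [hit_criteria()] gene by gene and records
#' per-criterion diagnostics for every gene regardless of pass/fail.
#' Infinite Z-scores (zero-SD references) exceed any finite threshold.
#'
#' @param z Z-score matrix from [zscore()] (may be `NULL` when
#'   `crit$metric == "fold_change"`).
#' @param fc Fold-change matrix from [fold_change()].
#' @param sheet Sample sheet identifying cases and controls.
#' @param crit A [hit_criteria()] object.
#' @return data.frame of class `hit_table`: one row per gene with
#'   `n_cases_positive`, `n_controls_positive`, `max_case_signal`,
#'   `max_control_signal`, `strong_case_present`, `passed`,
#'   `failed_criteria`.
#' @export
call_hits <- function(z, fc, sheet, crit = hit_criteria()) {
  sheet <- validate_sample_sheet(sheet)
  M <- if (crit$metric == "zscore") z else fc
  if (is.null(M)) stop("metric matrix (", crit$metric, ") is missing")
  cases <- intersect(samples_with_role(sheet, "case"), colnames(M))
  ctrls <- intersect(samples_with_role(sheet, "control"), colnames(M))
  if (length(cases) == 0 || length(ctrls) == 0)
    stop("metric matrix lacks case or control samples from the sheet")
  if (!all(cases %in% colnames(fc))) stop("fold-change matrix missing case samples")
  pos <- if (crit$strict_inequality) M > crit$positive_threshold else M >= crit$positive_threshold
  n_case_pos <- rowSums(pos[, cases, drop = FALSE])
  n_ctrl_pos <- rowSums(pos[, ctrls, drop = FALSE])
  max_case <- apply(M[, cases, drop = FALSE], 1, max)
  max_ctrl <- apply(M[, ctrls, drop = FALSE], 1, max)
  strong <- rowSums(pos[, cases, drop = FALSE] &
                      fc[rownames(M), cases, drop = FALSE] >= crit$strong_fc_min) >= 1

  c1 <- n_case_pos / length(cases) >= crit$case_min_frac
  ctrl_limit <- if (!is.null(crit$control_max_frac))
    ceiling(crit$control_max_frac * length(ctrls)) else crit$control_max_count
  c2 <- n_ctrl_pos < ctrl_limit
  c3 <- strong
  c4 <- if (crit$dominance_rule) max_ctrl <= max_case else rep(TRUE, nrow(M))

  failed <- mapply(function(a, b, d, e) {
    paste(c("case_frac", "control_limit", "strong_case", "dominance")[!c(a, b, d, e)],
          collapse = ",")
  }, c1, c2, c3, c4)
  out <- data.frame(gene_id = rownames(M),
                    n_cases_positive = n_case_pos,
                    n_controls_positive = n_ctrl_pos,
                    max_case_signal = max_case,
                    max_control_signal = max_ctrl,
                    strong_case_present = c3,
                    passed = c1 & c2 & c3 & c4,
                    failed_criteria = failed,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "criteria") <- crit
  attr(out, "n_cases") <- length(cases)
  attr(out, "n_controls") <- length(ctrls)
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Apparent hits as a function of control-cohort size
#'
#' Randomly downsamples the healthy controls to each requested size
#' (without replacement, `reps` independent draws per size), recomputes
#' the Z-scores against each downsampled control set — the reference is
#' rebuilt, never sliced from the full-cohort Z-scores — and recounts
#' genes passing `crit`. The fraction-mode control limit scales with the
#' downsampled size.
#'
#' @param fc Fold-change matrix over cases and the full control cohort.
#' @param sheet Sample sheet.
#' @param crit A [hit_criteria()] object.
#' @param sizes Control-set sizes to draw.
#' @param reps Random draws per size.
#' @param seed Integer seed governing all draws.
#' @return List of class `downsampling_curve` with `summary` (per size:
#'   mean and SD of apparent hits) and `per_rep` (per-rep counts), plus
#'   the seed.
#' @export
downsample_controls <- function(fc, sheet, crit = hit_criteria(),
                                sizes = c(5, 10, 25, 50, 100, 150),
                                reps = 10, seed = 1L) {
  sheet <- validate_sample_sheet(sheet)
  ctrls <- intersect(samples_with_role(sheet, "control"), colnames(fc))
  if (any(sizes > length(ctrls)))
    stop("requested control-set size exceeds available controls (", length(ctrls), ")")
  if (reps < 1) stop("reps must be >= 1")
  cases <- intersect(samples_with_role(sheet, "case"), colnames(fc))
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  per_rep <- expand.grid(size = sizes, rep = seq_len(reps))
  per_rep$apparent_hits <- NA_real_
  for (i in seq_len(nrow(per_rep))) {
    sub <- sample(ctrls, per_rep$size[i])
    sub_sheet <- sheet[sheet$sample_id %in% c(cases, sub), , drop = FALSE]
    fc_sub <- fc[, c(cases, sub), drop = FALSE]
    z_sub <- zscore(fc_sub, sub_sheet)
    ht <- call_hits(z_sub, fc_sub, sub_sheet, crit)
    per_rep$apparent_hits[i] <- sum(ht$passed)
  }
  .Random.seed_restore(old)
  summ <- do.call(rbind, lapply(sizes, function(s) {
    x <- per_rep$apparent_hits[per_rep$size == s]
    data.frame(size = s, mean_hits = mean(x),
               sd_hits = if (length(x) > 1) stats::sd(x) else 0)
  }))
  structure(list(summary = summ, per_rep = per_rep, seed = as.integer(seed),
                 criteria = crit),
            class = "downsampling_curve")
}

#' Overlap of hits between two cohorts
#'
#' For each gene passing in cohort A, counts positive samples in cohort
#' B on B's metric matrix at the criteria's positivity threshold, and
#' reports shared, A-only, and (when a B hit table is supplied) B-only
#' genes. A gene is "shared" when it passed in A and at least one B
#' sample is positive for it.
#'
#' @param hits_a `hit_table` for cohort A.
#' @param metric_b Metric matrix (genes x cohort-B samples) on the same
#'   metric the criteria use; columns should be B's case samples.
#' @param crit A [hit_criteria()] object (positivity threshold reused).
#' @param hits_b Optional `hit_table` for cohort B, for the B-only list.
#' @return List with `per_gene` (data.frame gene_id / n_b_positive),
#'   `shared`, `a_only`, `b_only`.
#' @export
cross_cohort_overlap <- function(hits_a, metric_b, crit = hit_criteria(),
                                 hits_b = NULL) {
  genes_a <- hits_a$gene_id[hits_a$passed]
  common <- intersect(genes_a, rownames(metric_b))
  if (length(genes_a) && length(common) == 0)
    warning("gene sets are disjoint; overlap is empty")
  n_pos <- stats::setNames(integer(length(genes_a)), genes_a)
  if (length(common)) {
    Mb <- metric_b[common, , drop = FALSE]
    pos <- if (crit$strict_inequality) Mb > crit$positive_threshold else Mb >= crit$positive_threshold
    n_pos[common] <- rowSums(pos)
  }
  shared <- names(n_pos)[n_pos >= 1]
  b_only <- if (!is.null(hits_b)) setdiff(hits_b$gene_id[hits_b$passed], genes_a) else character(0)
  list(per_gene = data.frame(gene_id = names(n_pos), n_b_positive = as.integer(n_pos),
                             row.names = NULL, stringsAsFactors = FALSE),
       shared = shared, a_only = setdiff(genes_a, shared), b_only = b_only)
}
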