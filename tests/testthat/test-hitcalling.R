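# Construct a toy cohort where hit status per gene is fully controlled.
toy_cohort <- function(n_cases = 128, n_controls = 186) {
  sheet <- data.frame(
    sample_id = c(sprintf("ca%03d", seq_len(n_cases)),
                  sprintf("co%03d", seq_len(n_controls))),
    role = rep(c("case", "control"), c(n_cases, n_controls)),
    stringsAsFactors = FALSE)
  sheet
}

toy_matrices <- function(sheet, z_cases, z_controls, fc_cases = NULL) {
  genes <- rownames(z_cases)
  cases <- sheet$sample_id[sheet$role == "case"]
  ctrls <- sheet$sample_id[sheet$role == "control"]
  z <- cbind(z_cases, z_controls)
  colnames(z) <- c(cases, ctrls)
  if (is.null(fc_cases)) fc_cases <- z_cases
  fc <- cbind(fc_cases, z_controls)
  colnames(fc) <- c(cases, ctrls)
  rownames(z) <- rownames(fc) <- genes
  list(z = z, fc = fc)
}

test_that("the four shared-hit criteria gate genes as specified", {
  sheet <- toy_cohort()
  zc <- matrix(1, nrow = 4, ncol = 128,
               dimnames = list(paste0("g", 1:4), NULL))
  zk <- matrix(1, nrow = 4, ncol = 186)
  fcc <- zc
  # g1: 13/128 cases positive (10.2%), one at FC 60, controls quiet -> pass
  zc["g1", 1:13] <- 15; fcc["g1", 1] <- 60
  # g2: positive cases but one control outranks every case -> dominance fail
  zc["g2", 1:13] <- 15; fcc["g2", 1] <- 60; zk[2, 1] <- 99
  # g3: only 12/128 cases positive (9.4%) -> case-fraction fail
  zc["g3", 1:12] <- 15; fcc["g3", 1] <- 60
  # g4: enough positives but none with FC >= 50 -> strong-case fail
  zc["g4", 1:13] <- 15; fcc["g4", 1:13] <- 20
  tm <- toy_matrices(sheet, zc, zk, fcc)
  ht <- call_hits(tm$z, tm$fc, sheet, hit_criteria())
  expect_identical(ht$passed, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(ht$failed_criteria[2], "dominance")
  expect_identical(ht$failed_criteria[3], "case_frac")
  expect_identical(ht$failed_criteria[4], "strong_case")
  expect_identical(ht$n_cases_positive[1], 13)
  expect_identical(ht$n_controls_positive[2], 1)
})

test_that("control limit modes: fraction (ceiling) and absolute (strict <)", {
  sheet <- toy_cohort(n_cases = 20, n_controls = 100)
  zc <- matrix(15, nrow = 1, ncol = 20, dimnames = list("g1", NULL))
  fcc <- matrix(60, nrow = 1, ncol = 20)
  # 2% of 100 controls -> limit ceiling(2) = 2; 1 positive control passes, 2 fail
  for (npos in 1:2) {
    zk <- matrix(1, nrow = 1, ncol = 100); zk[1, seq_len(npos)] <- 11
    # keep dominance satisfied: controls below the top case
    tm <- toy_matrices(sheet, zc, zk, fcc)
    ht_frac <- call_hits(tm$z, tm$fc, sheet, hit_criteria(control_max_frac = 0.02))
    expect_identical(ht_frac$passed, npos < 2)
    ht_abs <- call_hits(tm$z, tm$fc, sheet,
                        hit_criteria(control_max_frac = NULL, control_max_count = 2))
    expect_identical(ht_abs$passed, npos < 2)
  }
  expect_error(hit_criteria(control_max_frac = 0.02, control_max_count = 2),
               "exactly one")
})

test_that("strict-inequality and fold-change-metric presets change positivity", {
  sheet <- toy_cohort(n_cases = 10, n_controls = 10)
  zc <- matrix(10, nrow = 1, ncol = 10, dimnames = list("g1", NULL))  # exactly at threshold
  zk <- matrix(0, nrow = 1, ncol = 10)
  fcc <- matrix(60, nrow = 1, ncol = 10)
  tm <- toy_matrices(sheet, zc, zk, fcc)
  expect_true(call_hits(tm$z, tm$fc, sheet, hit_criteria())$n_cases_positive == 10)
  strict <- hit_criteria(strict_inequality = TRUE,
                         control_max_frac = NULL, control_max_count = 2)
  expect_identical(call_hits(tm$z, tm$fc, sheet, strict)$n_cases_positive, 0)

  fc10 <- hit_criteria_preset("caption_fc10")
  ht <- call_hits(NULL, tm$fc, sheet, fc10)   # judged on FC, z not needed
  expect_identical(ht$n_cases_positive, 10)
  expect_error(call_hits(NULL, tm$fc, sheet, hit_criteria()), "missing")
})

test_that("call_hits equals a naive triple-loop reference implementation", {
  d <- random_gene_dataset(n_genes = 20, n_cases = 12, n_controls = 15,
                           n_mock = 3, seed = 31)
  fc <- fold_change(normalize_counts(d$gene), d$sheet)
  z <- zscore(fc, d$sheet)
  # permissive thresholds so noise genes can pass every branch
  crit <- hit_criteria(positive_threshold = 1.5, case_min_frac = 0.25,
                       control_max_frac = 0.15, strong_fc_min = 2)
  ht <- call_hits(z, fc, d$sheet, crit)
  cases <- d$sheet$sample_id[d$sheet$role == "case"]
  ctrls <- d$sheet$sample_id[d$sheet$role == "control"]
  for (g in rownames(z)) {
    ncp <- 0; nkp <- 0; strong <- FALSE; mxc <- -Inf; mxk <- -Inf
    for (s in cases) {
      if (z[g, s] >= crit$positive_threshold) {
        ncp <- ncp + 1
        if (fc[g, s] >= crit$strong_fc_min) strong <- TRUE
      }
      mxc <- max(mxc, z[g, s])
    }
    for (s in ctrls) {
      if (z[g, s] >= crit$positive_threshold) nkp <- nkp + 1
      mxk <- max(mxk, z[g, s])
    }
    pass <- (ncp / length(cases) >= crit$case_min_frac) &&
      (nkp < ceiling(crit$control_max_frac * length(ctrls))) &&
      strong && (mxk <= mxc)
    row <- ht[ht$gene_id == g, ]
    expect_identical(row$passed, pass)
    expect_identical(row$n_cases_positive, ncp)
    expect_identical(row$n_controls_positive, nkp)
    expect_equal(row$max_case_signal, mxc)
    expect_equal(row$max_control_signal, mxk)
  }
})

test_that("adding a positive control can only hurt a gene's pass status", {
  sheet <- toy_cohort(n_cases = 20, n_controls = 50)
  zc <- matrix(1, nrow = 1, ncol = 20, dimnames = list("g1", NULL))
  zc[1, 1:5] <- 15
  fcc <- zc; fcc[1, 1] <- 60
  zk <- matrix(1, nrow = 1, ncol = 50)
  crit <- hit_criteria(case_min_frac = 0.2, control_max_frac = NULL,
                       control_max_count = 2)
  tm <- toy_matrices(sheet, zc, zk, fcc)
  expect_true(call_hits(tm$z, tm$fc, sheet, crit)$passed)
  # grow the positive-control count; pass status is non-increasing
  prev <- TRUE
  for (npos in 1:3) {
    zk2 <- zk; zk2[1, seq_len(npos)] <- 12
    tm2 <- toy_matrices(sheet, zc, zk2, fcc)
    cur <- call_hits(tm2$z, tm2$fc, sheet, crit)$passed
    expect_true(!cur | prev)
    prev <- cur
  }
  expect_false(prev)
})

test_that("downsampling at full size degenerates to plain hit calling and is seeded", {
  d <- random_gene_dataset(n_genes = 25, n_cases = 10, n_controls = 20,
                           n_mock = 3, seed = 37)
  fc <- fold_change(normalize_counts(d$gene), d$sheet)
  crit <- hit_criteria(positive_threshold = 2, case_min_frac = 0.2,
                       control_max_frac = 0.15, strong_fc_min = 2)
  full <- call_hits(zscore(fc, d$sheet), fc, d$sheet, crit)
  curve <- downsample_controls(fc, d$sheet, crit, sizes = 20, reps = 1, seed = 1)
  expect_identical(curve$per_rep$apparent_hits, as.numeric(sum(full$passed)))

  a <- downsample_controls(fc, d$sheet, crit, sizes = c(5, 10), reps = 3, seed = 99)
  b <- downsample_controls(fc, d$sheet, crit, sizes = c(5, 10), reps = 3, seed = 99)
  expect_identical(a$per_rep, b$per_rep)
  expect_error(downsample_controls(fc, d$sheet, crit, sizes = 21), "exceeds")
})

test_that("cross-cohort overlap reports shared and exclusive genes", {
  ht <- data.frame(gene_id = c("g1", "g2", "g3"),
                   passed = c(TRUE, TRUE, FALSE))
  class(ht) <- c("hit_table", "data.frame")
  mb <- rbind(g1 = c(0, 1), g2 = c(12, 0), g3 = c(0, 0))
  colnames(mb) <- c("b1", "b2")
  ov <- cross_cohort_overlap(ht, mb, hit_criteria())
  expect_identical(ov$shared, "g2")
  expect_identical(ov$a_only, "g1")
  expect_identical(ov$per_gene$n_b_positive[ov$per_gene$gene_id == "g2"], 1L)

  # identical hit tables -> full overlap
  ov2 <- cross_cohort_overlap(ht, mb, hit_criteria(), hits_b = ht)
  expect_length(ov2$b_only, 0)
  expect_warning(cross_cohort_overlap(ht, matrix(0, 1, 1, dimnames = list("x", "b")),
                                      hit_criteria()),
                 "disjoint")
})

test_that("two cohorts sharing one spiked gene report exactly that overlap", {
  shared_gene <- "G0001"
  mk <- function(dg, seed) {
    cfg <- sim_config(n_genes = 150, n_cases = 15, n_controls = 30, n_mock = 4,
                      n_private = 1, disease_genes = dg, penetrance = 0.6,
                      disease_effect = 100, seed = seed)
    ds <- simulate_dataset(cfg)
    g <- aggregate_to_gene(ds$counts, ds$map)
    fc <- fold_change(normalize_counts(g), ds$sheet)
    z <- zscore(fc, ds$sheet)
    cases <- ds$sheet$sample_id[ds$sheet$role == "case"]
    list(ht = call_hits(z, fc, ds$sheet,
                        hit_criteria(case_min_frac = 0.2)),
         z_cases = z[, cases, drop = FALSE])
  }
  a <- mk(c(shared_gene, "G0002"), seed = 41)
  b <- mk(c(shared_gene, "G0003"), seed = 43)
  ov <- cross_cohort_overlap(a$ht, b$z_cases, hit_criteria(), hits_b = b$ht)
  expect_identical(ov$shared, shared_gene)
  expect_identical(ov$a_only, "G0002")
  expect_identical(ov$b_only, "G0003")
})
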