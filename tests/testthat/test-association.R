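# Gene-level logistic regression, FDR, candidate selection, and the
# carrier-model Fisher exact test.

test_that("a binary burden reproduces the analytic 2x2 odds ratio", {
  burden <- c(rep(1, 10), rep(0, 26), rep(1, 11), rep(0, 108))
  y <- c(rep(1, 36), rep(0, 119))
  res <- fit_gene_mlr(1 - burden, y)
  expect_equal(res$or, 10 * 108 / (26 * 11), tolerance = 1e-4)
})

test_that("logistic regression recovers a known burden effect", {
  set.seed(4)
  burden <- runif(2000)
  y <- rbinom(2000, 1, plogis(-1 + 2 * burden))
  res <- fit_gene_mlr(1 - burden, y)
  expect_lt(abs(res$beta - 2), 0.2)
  expect_true(res$ci_low < res$or && res$or < res$ci_high)
})

test_that("degenerate fits return NA: zero variance, tiny groups, separation", {
  y <- rep(c(1, 0), each = 20)
  expect_true(is.na(fit_gene_mlr(rep(1, 40), y)$p))
  expect_warning(res <- fit_gene_mlr(runif(40), c(rep(1, 5), rep(0, 35))),
                 "fewer than")
  expect_true(is.na(res$p))
  # complete separation
  sep <- c(rep(0.2, 20), rep(0.9, 20))
  expect_true(is.na(fit_gene_mlr(sep, y)$p))
})

test_that("bh_fdr steps up over non-missing entries and keeps NA", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(0.01, NA, 0.03)), c(0.02, NA, 0.03))
  q <- bh_fdr(c(0.5, NA, 0.001, 0.04))
  expect_true(is.na(q[2]))
  expect_true(all(q[!is.na(q)] >= c(0.5, 0.001, 0.04)[c(1, 2, 3)] - 1e-12))
})

test_that("bh_fdr equals the brute-force min-over-tail definition", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      q[o[i]] <- min(vapply(i:m, function(j) m * p[o[j]] / j, numeric(1)), 1)
    }
    q
  }
  set.seed(123)
  for (rep in 1:1000) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("candidate selection fires on either test family", {
  res <- data.frame(
    gene = c("BRPF3", "PPFIBP1", "CGREF1", "NONE", "NAGENE"),
    stratum = "male",
    mlr_fdr_q = c(0.2459, 0.3822, 1.0, 0.6, NA),
    skato_fdr_q = c(NA, 0.018, 0.125, 0.5, NA),
    stringsAsFactors = FALSE)
  sel <- select_candidates(res, 0.25)
  expect_setequal(sel$gene, c("BRPF3", "PPFIBP1", "CGREF1"))
})

test_that("carrier-model Fisher test handles symmetric and empty tables", {
  sym <- variant_fisher(c(9, 1, 0), c(9, 1, 0))
  expect_equal(sym$or, 1)
  expect_equal(sym$p, 1)
  zero <- variant_fisher(c(0, 0, 0), c(0, 0, 0))
  expect_equal(zero$p, 1)
  expect_true(is.na(zero$or))
  expect_error(variant_fisher(c(-1, 0, 0), c(1, 0, 0)), "non-negative")
})

test_that("Fisher p is invariant to group swap and OR maps to reciprocal", {
  set.seed(8)
  for (rep in 1:20) {
    nr <- c(sample(0:30, 1), sample(0:10, 1), sample(0:3, 1))
    pr <- c(sample(0:100, 1), sample(0:15, 1), sample(0:3, 1))
    a <- variant_fisher(nr, pr)
    b <- variant_fisher(pr, nr)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    if (is.finite(a$or) && !is.na(a$or) && a$or > 0 &&
        is.finite(b$or) && !is.na(b$or)) {
      expect_equal(a$or, 1 / b$or, tolerance = 1e-12)
    }
  }
})

test_that("covariate screening keeps only group-differing covariates", {
  set.seed(9)
  n <- 200
  y <- rep(c(1, 0), each = n / 2)
  ph <- data.frame(age = rnorm(n, 50 + 5 * y, 5),       # differs
                   hads_a = rnorm(n, 8, 3),             # does not
                   sex = sample(c("male", "female"), n, TRUE),
                   stringsAsFactors = FALSE)
  sel <- screen_covariates(ph, y, c("age", "hads_a", "sex"))
  expect_true("age" %in% sel)
  expect_false("hads_a" %in% sel)
})

test_that("two-step run produces coherent per-stratum tables", {
  cohort <- small_cohort(seed = 77L, n = 220L, genes = 6L)
  oc <- suppressWarnings(derive_outcomes(cohort$phenotypes,
                                         imputation_config(seed = 77)))
  geno <- cohort$genotypes[oc$sample_id, , drop = FALSE]
  gvb <- compute_gvb(geno, cohort$variants)
  res <- suppressWarnings(
    run_two_step(gvb, geno, cohort$variants, oc, cohort$phenotypes,
                 min_per_group = 5))
  gr <- res$gene_results
  expect_setequal(unique(gr$stratum), c("total", "male", "female"))
  expect_equal(nrow(gr), 6 * 3)
  # q >= p wherever both exist
  ok <- !is.na(gr$mlr_p)
  expect_true(all(gr$mlr_fdr_q[ok] >= gr$mlr_p[ok] - 1e-12))
  ok <- !is.na(gr$skato_p)
  expect_true(all(gr$skato_fdr_q[ok] >= gr$skato_p[ok] - 1e-12))
  # NA MLR results exactly when the burden is constant in the stratum
  for (i in seq_len(nrow(gr))) {
    stratum_mask <- if (gr$stratum[i] == "total") rep(TRUE, nrow(oc))
                    else cohort$phenotypes$sex[match(oc$sample_id,
                          cohort$phenotypes$sample_id)] == gr$stratum[i]
    use <- stratum_mask & oc$group %in% c("ER_neg_REM_neg", "ER_pos_REM_pos")
    if (length(unique(gvb[use, gr$gene[i]])) < 2) {
      expect_true(is.na(gr$mlr_p[i]))
    }
  }
  # every candidate's variants appear in step 2
  if (nrow(res$candidates) > 0) {
    for (g in res$candidates$gene)
      expect_true(any(res$variant_results$gene == g))
  }
  # output writer round-trips
  dir <- tempfile(); paths <- write_association_tsv(res, dir)
  expect_true(all(file.exists(paths)))
})

test_that("a male-specific planted effect is detected only in males", {
  causal <- data.frame(gene = "G0001", effect = 2.0, stratum = "male",
                       stringsAsFactors = FALSE)
  cfg <- sim_config(n_samples = 900, n_genes = 40, variants_per_gene = 10,
                    causal_genes = causal, seed = 314)
  cohort <- simulate_cohort(cfg)
  oc <- suppressWarnings(derive_outcomes(cohort$phenotypes,
                                         imputation_config(seed = 314)))
  geno <- cohort$genotypes[oc$sample_id, , drop = FALSE]
  gvb <- compute_gvb(geno, cohort$variants)
  res <- suppressWarnings(run_two_step(gvb, geno, cohort$variants, oc,
                                       cohort$phenotypes))
  gr <- res$gene_results[res$gene_results$gene == "G0001", ]
  male <- gr[gr$stratum == "male", ]
  female <- gr[gr$stratum == "female", ]
  expect_lt(male$mlr_fdr_q, 0.25)
  expect_true(is.na(female$mlr_fdr_q) || female$mlr_fdr_q >= 0.25)
  expect_true(is.na(female$skato_fdr_q) || female$skato_fdr_q >= 0.25)
})

test_that("a stratum without extreme-group samples is skipped with a warning", {
  cohort <- simulate_cohort(sim_config(n_samples = 120, n_genes = 3,
                                       variants_per_gene = 4, prop_male = 0,
                                       seed = 2))
  oc <- suppressWarnings(derive_outcomes(cohort$phenotypes,
                                         imputation_config(seed = 2)))
  geno <- cohort$genotypes[oc$sample_id, , drop = FALSE]
  gvb <- compute_gvb(geno, cohort$variants)
  warnings_seen <- capture_warnings(
    res <- run_two_step(gvb, geno, cohort$variants, oc, cohort$phenotypes,
                        min_per_group = 5))
  expect_true(any(grepl("stratum 'male'", warnings_seen)))
  expect_setequal(unique(res$gene_results$stratum), c("total", "female"))
})

test_that("fdr_threshold = 1 sends every testable gene to step 2", {
  cohort <- small_cohort(seed = 31L, n = 160L, genes = 4L)
  oc <- suppressWarnings(derive_outcomes(cohort$phenotypes,
                                         imputation_config(seed = 31)))
  geno <- cohort$genotypes[oc$sample_id, , drop = FALSE]
  gvb <- compute_gvb(geno, cohort$variants)
  res <- suppressWarnings(
    run_two_step(gvb, geno, cohort$variants, oc, cohort$phenotypes,
                 fdr_threshold = 1.0000001, min_per_group = 5,
                 strata = "total"))
  gr <- res$gene_results
  testable <- gr$gene[!is.na(gr$mlr_fdr_q) | !is.na(gr$skato_fdr_q)]
  expect_setequal(res$candidates$gene, unique(testable))
})
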