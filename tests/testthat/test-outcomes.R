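# Outcome derivation: inclusion, imputation, classification, pooling.

test_that("inclusion needs an early visit (week 1 or 2) plus week 3", {
  p <- rbind(
    make_pheno("A", w1 = NA, w2 = 16, w3 = 15),          # weeks {0,2,3}
    make_pheno("B", w1 = NA, w2 = NA, w3 = 15),          # weeks {0,3}
    make_pheno("C", w1 = 18, w2 = 16, w3 = NA),          # week 3 missing
    make_pheno("D", w1 = 18, w2 = NA, w3 = 15))          # weeks {0,1,3}
  expect_equal(check_inclusion(p), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("20% early-improvement boundary and remission cut are exact", {
  p <- rbind(make_pheno("A", w0 = 20, w2 = 16, w12 = 7),
             make_pheno("B", w0 = 20, w2 = 17, w12 = 8),
             make_pheno("C", w0 = 20, w2 = 10, w12 = 12))
  lab <- classify_outcome(p)
  expect_equal(lab$early_improvement, c(TRUE, FALSE, TRUE))
  expect_equal(lab$remission, c(TRUE, FALSE, FALSE))
  expect_equal(as.character(lab$group),
               c("ER_pos_REM_pos", "ER_neg_REM_neg", "excluded"))
})

test_that("group assignment is the exhaustive function of the two booleans", {
  grid <- expand.grid(ei = c(TRUE, FALSE), rem = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    w2 <- if (grid$ei[i]) 10 else 19
    w12 <- if (grid$rem[i]) 5 else 15
    lab <- classify_outcome(make_pheno(w0 = 20, w2 = w2, w12 = w12))
    expected <- if (grid$ei[i] && grid$rem[i]) "ER_pos_REM_pos"
                else if (!grid$ei[i] && !grid$rem[i]) "ER_neg_REM_neg"
                else "excluded"
    expect_equal(as.character(lab$group), expected)
  }
})

test_that("complete tables pass through imputation untouched", {
  p <- rbind(make_pheno("A"), make_pheno("B", w0 = 25, w12 = 20))
  out <- impute_hamd(p, imputation_config(n_imputations = 3, seed = 1))
  expect_length(out, 3L)
  for (d in out) expect_equal(d, p)
})

test_that("imputation is deterministic, only after week 3, never alters data", {
  cohort <- small_cohort(seed = 21L, n = 120L, genes = 3L)
  p <- cohort$phenotypes
  cfg <- imputation_config(n_imputations = 2, seed = 99)
  a <- impute_hamd(p, cfg)
  b <- impute_hamd(p, cfg)
  expect_identical(a, b)
  comp <- a[[1]]
  expect_false(anyNA(comp[, hamd_cols()]))
  for (col in hamd_cols()) {
    obs <- !is.na(p[[col]])
    expect_equal(comp[[col]][obs], p[[col]][obs])
  }
  # imputed values live on the legal integer score range
  expect_true(all(comp$hamd_w12 >= 0 & comp$hamd_w12 <= 52))
  expect_true(all(comp$hamd_w12 == round(comp$hamd_w12)))
})

test_that("PMM recovers withheld week-12 scores better than the marginal SD", {
  # trajectories with a known linear decay; 20% MCAR at week 12
  set.seed(55)
  n <- 250
  w0 <- round(rnorm(n, 22, 3)); w0 <- pmax(w0, 14)
  slope <- runif(n, 0.4, 1.4)
  p <- data.frame(sample_id = sprintf("S%03d", 1:n),
                  sex = sample(c("male", "female"), n, TRUE),
                  age = round(rnorm(n, 45, 10)),
                  hads_a = round(rnorm(n, 8, 3)),
                  stringsAsFactors = FALSE)
  for (wk in c(0, 1, 2, 3, 6, 9, 12)) {
    p[[paste0("hamd_w", wk)]] <- pmax(round(w0 - slope * wk +
                                              rnorm(n, 0, 1)), 0)
  }
  truth <- p$hamd_w12
  miss <- runif(n) < 0.2
  p$hamd_w12[miss] <- NA
  out <- impute_hamd(p, imputation_config(n_imputations = 5, seed = 3))
  imp <- rowMeans(vapply(out, function(d) d$hamd_w12, numeric(n)))[miss]
  mae <- mean(abs(imp - truth[miss]))
  expect_lt(mae, sd(truth))
})

test_that("an entirely missing predictor is a configuration error", {
  p <- rbind(make_pheno("A"), make_pheno("B", w12 = NA))
  p$hads_a <- NA
  expect_error(impute_hamd(p, imputation_config()), "hads_a")
})

test_that("pooling takes majority votes and flags exact ties", {
  lab <- function(ei, rem) {
    data.frame(sample_id = "A", early_improvement = ei, remission = rem,
               group = factor(ifelse(ei & rem, "ER_pos_REM_pos",
                                     ifelse(!ei & !rem, "ER_neg_REM_neg",
                                            "excluded")),
                              levels = c("ER_neg_REM_neg", "ER_pos_REM_pos",
                                         "excluded")),
               stringsAsFactors = FALSE)
  }
  agree <- pool_outcomes(list(lab(TRUE, TRUE), lab(TRUE, TRUE),
                              lab(TRUE, TRUE)))
  expect_true(agree$early_improvement && agree$remission && !agree$tie)
  maj <- pool_outcomes(list(lab(TRUE, TRUE), lab(TRUE, TRUE),
                            lab(TRUE, FALSE), lab(TRUE, FALSE),
                            lab(TRUE, TRUE)))
  expect_true(maj$remission)      # 3 of 5 vote remission
  tie <- pool_outcomes(list(lab(TRUE, TRUE), lab(TRUE, FALSE)))
  expect_true(tie$tie)
  expect_true(tie$remission)      # tie resolved from the first imputation
})

test_that("fully observed cohorts give labels invariant to imputation settings", {
  cohort <- simulate_cohort(sim_config(n_samples = 80, n_genes = 2,
                                       variants_per_gene = 4,
                                       missing_rate = 0, seed = 5))
  a <- derive_outcomes(cohort$phenotypes,
                       imputation_config(n_imputations = 2, seed = 1))
  b <- derive_outcomes(cohort$phenotypes,
                       imputation_config(n_imputations = 7, seed = 123))
  expect_identical(a, b)
})
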