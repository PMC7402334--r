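# Two-step extreme-phenotype association.
#
# Step 1 (gene level, per stratum): covariate-adjusted logistic regression
# of extreme-group membership on the gene's burden (1 - GVB), and SKAT-O on
# the gene's rare-variant set; Benjamini-Hochberg FDR within each stratum x
# test family. Step 2 (variant level): dominant carrier-model Fisher exact
# tests on every variant of the candidate genes.

#' Logistic regression of extreme-group membership on gene burden
#'
#' Fits `outcome ~ burden + covariates` with `burden = 1 - GVB`, outcome
#' coded 1 for the poor-early-improvement / non-remission group, so an odds
#' ratio above 1 means deleterious burden raises the odds of eventual
#' non-remission. Returns `NA` results when the burden has zero variance
#' among analysed samples, when either group has fewer than `min_per_group`
#' samples, or when the fit does not converge (complete separation).
#'
#' @param gvb_scores per-sample GVB values for one gene.
#' @param outcome 0/1 vector (1 = non-remission extreme group), aligned with
#'   `gvb_scores`.
#' @param covariates optional numeric data.frame/matrix of adjustment
#'   covariates.
#' @param min_per_group minimum group size for a fit (default 10).
#' @return list with `p`, `or`, `ci_low`, `ci_high`, `beta`, `se`
#'   (all `NA` when not applicable).
#' @export
fit_gene_mlr <- function(gvb_scores, outcome, covariates = NULL,
                         min_per_group = 10L) {
  na_result <- list(p = NA_real_, or = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, beta = NA_real_, se = NA_real_)
  if (!is_binary01(outcome)) stopf("outcome must be coded 0/1")
  burden <- 1 - gvb_scores
  if (length(unique(burden)) < 2L) return(na_result)
  if (min(table(factor(outcome, levels = 0:1))) < min_per_group) {
    warnf("fewer than %d samples in a group; logistic model not fitted",
          min_per_group)
    return(na_result)
  }
  dat <- data.frame(.y = outcome, .burden = burden)
  if (!is.null(covariates) && NCOL(covariates) > 0L)
    dat <- cbind(dat, as.data.frame(covariates))
  fit <- tryCatch(
    suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(na_result)
  coefs <- summary(fit)$coefficients
  if (!".burden" %in% rownames(coefs)) return(na_result)
  beta <- coefs[".burden", "Estimate"]
  se <- coefs[".burden", "Std. Error"]
  # quasi-separation: Wald inference meaningless when the SE explodes
  if (!is.finite(se) || se > 50 || abs(beta) > 25) return(na_result)
  list(p = coefs[".burden", "Pr(>|z|)"], or = exp(beta),
       ci_low = exp(beta - 1.959964 * se), ci_high = exp(beta + 1.959964 * se),
       beta = beta, se = se)
}

#' Benjamini-Hochberg q-values with NA pass-through
#'
#' Step-up BH adjustment over the non-missing entries; `NA` p-values stay
#' `NA` and do not count toward the number of tests.
#'
#' @param pvals numeric vector of p-values, `NA` allowed.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvals) {
  q <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stopf("p-values must lie in [0, 1]")
  q[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  q
}

#' Select candidate genes from step-1 results
#'
#' A gene is carried to the variant-level step when either test family puts
#' it under the FDR threshold in that stratum.
#'
#' @param results gene-level result data.frame with columns `gene`,
#'   `stratum`, `mlr_fdr_q`, `skato_fdr_q`.
#' @param fdr_threshold screening threshold (default 0.25).
#' @return data.frame of selected `gene`/`stratum` pairs.
#' @export
select_candidates <- function(results, fdr_threshold = 0.25) {
  hit <- (!is.na(results$mlr_fdr_q) & results$mlr_fdr_q < fdr_threshold) |
    (!is.na(results$skato_fdr_q) & results$skato_fdr_q < fdr_threshold)
  out <- results[hit, c("gene", "stratum"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Carrier-model Fisher exact test for one variant
#'
#' Dominant coding: samples are dichotomised as carriers (>= 1 ALT allele,
#' het + hom) versus homozygous reference, giving the 2x2 table
#' `[[carriers_NR, ref_NR], [carriers_PR, ref_PR]]`. Reports the two-sided
#' exact p, the sample cross-product odds ratio (`Inf` when the remission
#' group has no carrier but the non-remission group does), and the Woolf
#' logit 95% CI, which is `NA` whenever any cell is zero.
#'
#' @param nr_counts integer vector `c(ref, het, hom)` in the non-remission
#'   (poor early improvement) extreme group.
#' @param pr_counts integer vector `c(ref, het, hom)` in the remission
#'   (early improvement) extreme group.
#' @return list with the table cells (`a`,`b`,`c`,`d`), `p`, `or`,
#'   `ci_low`, `ci_high`.
#' @export
variant_fisher <- function(nr_counts, pr_counts) {
  stopifnot(length(nr_counts) == 3L, length(pr_counts) == 3L)
  if (any(c(nr_counts, pr_counts) < 0) ||
      any(c(nr_counts, pr_counts) != round(c(nr_counts, pr_counts))))
    stopf("genotype counts must be non-negative integers")
  a <- nr_counts[2] + nr_counts[3]; b <- nr_counts[1]   # NR carriers / ref
  cc <- pr_counts[2] + pr_counts[3]; d <- pr_counts[1]  # PR carriers / ref
  tab <- matrix(c(a, b, cc, d), nrow = 2L, byrow = TRUE)
  if (sum(tab) == 0L)
    return(list(a = a, b = b, c = cc, d = d, p = 1,
                or = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  p <- stats::fisher.test(tab)$p.value
  or <- if (b == 0 || cc == 0) {
    if (a > 0 && d > 0) Inf else NA_real_
  } else {
    (a * d) / (b * cc)
  }
  if (all(tab > 0)) {
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    ci <- exp(log(or) + c(-1, 1) * 1.959964 * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  list(a = a, b = b, c = cc, d = d, p = min(p, 1), or = or,
       ci_low = ci[1], ci_high = ci[2])
}

#' Univariate covariate screen between the two extreme groups
#'
#' Candidate adjustment covariates are kept when they differ between the
#' extreme groups at p < 0.05 in a univariate test: Welch t-test for numeric
#' covariates, chi-square for categorical ones.
#'
#' @param phenotypes phenotype table restricted to analysed samples.
#' @param outcome 0/1 group vector aligned with `phenotypes` rows.
#' @param candidates covariate column names to screen.
#' @param alpha screening level (default 0.05).
#' @return character vector of selected covariate names.
#' @export
screen_covariates <- function(phenotypes, outcome,
                              candidates = c("age", "sex", "hamd_w0", "hads_a"),
                              alpha = 0.05) {
  candidates <- intersect(candidates, names(phenotypes))
  keep <- vapply(candidates, function(cv) {
    x <- phenotypes[[cv]]
    if (length(unique(stats::na.omit(x))) < 2L) return(FALSE)
    p <- tryCatch({
      if (is.numeric(x)) stats::t.test(x ~ outcome)$p.value
      else suppressWarnings(stats::chisq.test(table(x, outcome))$p.value)
    }, error = function(e) NA_real_)
    !is.na(p) && p < alpha
  }, logical(1))
  candidates[keep]
}

covariate_design <- function(phenotypes, covariate_names) {
  if (length(covariate_names) == 0L) return(NULL)
  cols <- lapply(covariate_names, function(cv) {
    x <- phenotypes[[cv]]
    if (is.numeric(x)) x else as.numeric(factor(x)) - 1
  })
  names(cols) <- covariate_names
  as.data.frame(cols)
}

# Rare-variant selection per the configured AF source.
rare_variant_keys <- function(variants, genotypes, spec) {
  af <- switch(spec$af_source,
    reference_panel = {
      af <- variants$ref_af
      cohort <- colMeans(genotypes[, variants$key, drop = FALSE],
                         na.rm = TRUE) / 2
      ifelse(is.na(af), cohort, af)
    },
    cohort = colMeans(genotypes[, variants$key, drop = FALSE], na.rm = TRUE) / 2
  )
  maf <- pmin(af, 1 - af)
  variants$key[!is.na(maf) & maf < spec$af_threshold]
}

#' Run the full two-step association analysis
#'
#' Step 1 per stratum (`total`, `male`, `female`): for every gene, the
#' burden logistic regression ([fit_gene_mlr()]) with group GVB summaries,
#' and SKAT-O ([skat_o()]) on the gene's rare-variant set; BH-FDR is applied
#' separately within each stratum and test family. Step 2: every variant
#' (rare and common) of each candidate gene is tested with the carrier-model
#' Fisher exact test in the stratum where the gene was selected.
#'
#' @param gvb samples x genes GVB matrix.
#' @param genotypes samples x variants dosage matrix.
#' @param variants annotated variant table.
#' @param outcomes pooled outcome table from [derive_outcomes()].
#' @param phenotypes phenotype table (sex for strata, covariates for
#'   screening/adjustment).
#' @param covariates either a character vector of covariate columns to
#'   adjust for, or `NULL` to select them by [screen_covariates()].
#' @param spec a [rare_set_spec()] for the SKAT-O rare sets.
#' @param fdr_threshold step-1 screening threshold (default 0.25).
#' @param strata strata to analyse (default total, male, female).
#' @param min_per_group minimum extreme-group size per stratum.
#' @return list with `gene_results`, `candidates`, `variant_results`
#'   data.frames.
#' @export
run_two_step <- function(gvb, genotypes, variants, outcomes, phenotypes,
                         covariates = NULL, spec = rare_set_spec(),
                         fdr_threshold = 0.25,
                         strata = c("total", "male", "female"),
                         min_per_group = 10L) {
  stopifnot(identical(rownames(gvb), rownames(genotypes)))
  pheno <- phenotypes[match(rownames(gvb), phenotypes$sample_id), , drop = FALSE]
  lab <- outcomes[match(rownames(gvb), outcomes$sample_id), , drop = FALSE]
  genes <- colnames(gvb)
  rare_keys <- rare_variant_keys(variants, genotypes, spec)

  gene_results <- list()
  variant_results <- list()
  for (stratum in strata) {
    in_stratum <- if (stratum == "total") rep(TRUE, nrow(pheno))
                  else !is.na(pheno$sex) & pheno$sex == stratum
    use <- in_stratum & lab$group %in% c("ER_neg_REM_neg", "ER_pos_REM_pos")
    if (sum(use, na.rm = TRUE) == 0L) {
      warnf("stratum '%s' has no samples in the extreme groups; skipped", stratum)
      next
    }
    y <- as.integer(lab$group[use] == "ER_neg_REM_neg")
    ph_s <- pheno[use, , drop = FALSE]
    cov_names <- if (is.null(covariates)) {
      cands <- setdiff(c("age", "sex", "hamd_w0", "hads_a"),
                       if (stratum != "total") "sex" else character(0))
      screen_covariates(ph_s, y, cands)
    } else {
      setdiff(covariates, if (stratum != "total") "sex" else character(0))
    }
    cov_mat <- covariate_design(ph_s, cov_names)
    geno_s <- genotypes[use, , drop = FALSE]
    null_model <- skat_null_model(y, cov_mat)

    rows <- lapply(genes, function(g) {
      scores <- gvb[use, g]
      mlr <- fit_gene_mlr(scores, y, cov_mat, min_per_group = min_per_group)
      gk <- variants$key[variants$gene %in% g]
      rk <- intersect(gk, rare_keys)
      skato_p <- if (length(rk) >= 1L) {
        maf <- {
          af <- variants$ref_af[match(rk, variants$key)]
          cohort <- colMeans(geno_s[, rk, drop = FALSE], na.rm = TRUE) / 2
          m <- ifelse(is.na(af), cohort, if (spec$af_source == "cohort") cohort else af)
          pmin(m, 1 - m)
        }
        skat_o(geno_s[, rk, drop = FALSE], y, cov_mat, spec, maf = maf,
               null_model = null_model)$p
      } else NA_real_
      data.frame(
        gene = g, stratum = stratum, n_nr = sum(y == 1), n_pr = sum(y == 0),
        mlr_p = mlr$p, mlr_or = mlr$or,
        mlr_ci_low = mlr$ci_low, mlr_ci_high = mlr$ci_high,
        gvb_mean_nr = mean(scores[y == 1]), gvb_sd_nr = stats::sd(scores[y == 1]),
        gvb_mean_pr = mean(scores[y == 0]), gvb_sd_pr = stats::sd(scores[y == 0]),
        n_rare_variants = length(rk), skato_p = skato_p,
        stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$mlr_fdr_q <- bh_fdr(res$mlr_p)
    res$skato_fdr_q <- bh_fdr(res$skato_p)
    gene_results[[stratum]] <- res

    cand <- select_candidates(res, fdr_threshold)
    for (g in cand$gene) {
      vks <- variants$key[variants$gene %in% g]
      for (vk in vks) {
        dos <- geno_s[, vk]
        counts_of <- function(grp) {
          d <- dos[y == grp]
          d <- d[!is.na(d)]
          c(sum(d == 0), sum(d == 1), sum(d == 2))
        }
        nr <- counts_of(1L); pr <- counts_of(0L)
        ft <- variant_fisher(nr, pr)
        vrow <- variants[match(vk, variants$key), ]
        variant_results[[length(variant_results) + 1L]] <- data.frame(
          gene = g, stratum = stratum, key = vk,
          position = paste0(vrow$chrom, ":", vrow$pos),
          alt = paste(vrow$ref, ">", vrow$alt),
          rsid = vrow$rsid, sift = vrow$sift, cadd = vrow$cadd,
          ref_af = vrow$ref_af,
          nr_ref = nr[1], nr_het = nr[2], nr_hom = nr[3],
          pr_ref = pr[1], pr_het = pr[2], pr_hom = pr[3],
          fisher_p = ft$p, or = ft$or, ci_low = ft$ci_low, ci_high = ft$ci_high,
          stringsAsFactors = FALSE)
      }
    }
  }
  gene_results <- if (length(gene_results) > 0L) {
    do.call(rbind, c(gene_results, list(make.row.names = FALSE)))
  } else {
    data.frame()
  }
  variant_results <- if (length(variant_results) > 0L) {
    do.call(rbind, c(variant_results, list(make.row.names = FALSE)))
  } else {
    data.frame()
  }
  candidates <- if (nrow(gene_results) == 0L) data.frame() else
    select_candidates(gene_results, fdr_threshold)
  list(gene_results = gene_results, candidates = candidates,
       variant_results = variant_results)
}

#' Write association result tables as TSV
#'
#' Gene-level and variant-level tables mirror the layout of published
#' two-step results: `NA` is spelled `NA`, an infinite odds ratio is
#' spelled `Inf`.
#'
#' @param results list from [run_two_step()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_association_tsv <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "gene_results.tsv"),
             file.path(dir, "variant_results.tsv"),
             file.path(dir, "candidates.tsv"))
  utils::write.table(results$gene_results, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(results$variant_results, paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(results$candidates, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(paths)
}
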