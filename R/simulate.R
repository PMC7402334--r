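# Fully synthetic cohort generator: Hardy-Weinberg genotypes over a
# common+rare allele-frequency spectrum, SIFT/CADD annotations, covariates,
# and longitudinal HAM-D trajectories driven by a latent response class
# with optional planted gene effects. Emulates the data structure of an
# extreme-phenotype antidepressant-outcome cohort so every pipeline stage
# is testable without access to protected sequencing data.

#' Synthetic cohort configuration
#'
#' @param n_samples number of patients (default 1000, the cohort scale the
#'   design targets).
#' @param n_genes number of genes (default 200).
#' @param variants_per_gene exonic variants simulated per gene (default 10).
#' @param common_af_range,rare_af_range alternate-allele frequency ranges
#'   for common and rare variants.
#' @param prop_rare proportion of variants drawn from the rare range
#'   (default 0.7, mimicking the rare-heavy exome site-frequency balance).
#' @param p_deleterious probability a variant is deleterious, i.e. SIFT ~
#'   Uniform(0, 0.05); otherwise SIFT ~ Uniform(0.05, 1).
#' @param causal_genes data.frame with columns `gene`, `effect`
#'   (log-odds of non-remission per unit burden 1 - GVB) and `stratum`
#'   (`all`, `male`, `female`); default none.
#' @param intercept log-odds of the responder (remitting) class at zero
#'   burden; default `qlogis(0.426)` so the marginal remission rate sits
#'   near the 42.6% observed in naturalistic antidepressant cohorts.
#' @param p_partial_nonresponder among non-responders, probability of a
#'   partial-response trajectory (early improvement without remission);
#'   default 0.78, which together with `intercept` puts the marginal
#'   early-improvement rate near 83%.
#' @param baseline_mean,baseline_sd,baseline_min truncated-normal baseline
#'   HAM-D parameters (default mean 20, sd 4, lower bound 14 — the
#'   eligibility floor).
#' @param missing_rate per-visit missingness probability applied only to
#'   weeks after week 3 (scalar, default 0.10).
#' @param prop_male probability a sample is male (default 0.5).
#' @param score_noise_sd visit-level Gaussian noise on scores before
#'   rounding (default 1.5 HAM-D points).
#' @param seed master seed; genotype, phenotype and missingness draws use
#'   fixed substreams derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1000L, n_genes = 200L,
                       variants_per_gene = 10L,
                       common_af_range = c(0.01, 0.3),
                       rare_af_range = c(0.0005, 0.01),
                       prop_rare = 0.7, p_deleterious = 0.3,
                       causal_genes = NULL,
                       intercept = stats::qlogis(0.426),
                       p_partial_nonresponder = 0.78,
                       baseline_mean = 20, baseline_sd = 4, baseline_min = 14,
                       missing_rate = 0.10, prop_male = 0.5,
                       score_noise_sd = 1.5, seed = 1L) {
  stopifnot(n_samples >= 2, n_genes >= 1, variants_per_gene >= 1,
            prop_rare >= 0, prop_rare <= 1,
            p_deleterious >= 0, p_deleterious <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(causal_genes))
    stopifnot(all(c("gene", "effect", "stratum") %in% names(causal_genes)),
              all(causal_genes$stratum %in% c("all", "male", "female")))
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 variants_per_gene = as.integer(variants_per_gene),
                 common_af_range = common_af_range,
                 rare_af_range = rare_af_range,
                 prop_rare = prop_rare, p_deleterious = p_deleterious,
                 causal_genes = causal_genes, intercept = intercept,
                 p_partial_nonresponder = p_partial_nonresponder,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 baseline_min = baseline_min, missing_rate = missing_rate,
                 prop_male = prop_male, score_noise_sd = score_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_gene_names <- function(n) sprintf("G%04d", seq_len(n))

rtruncnorm_lower <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, 1), mean, sd)
}

#' Simulate annotated variants and Hardy-Weinberg genotypes
#'
#' Each variant's alternate-allele frequency is drawn from the rare or
#' common range; genotypes are binomial(2, AF) per sample (Hardy-Weinberg);
#' the drawn AF is recorded as the reference-panel frequency annotation.
#' SIFT scores follow the configured deleterious/tolerated mixture.
#'
#' @param config a [sim_config()].
#' @return list with `variants` and `genotypes` as in [read_annotated_vcf()].
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed * 10L + 1L)
  n <- config$n_samples
  genes <- sim_gene_names(config$n_genes)
  m <- config$n_genes * config$variants_per_gene
  gene_of <- rep(genes, each = config$variants_per_gene)
  chrom <- as.character(rep_len(1:22, config$n_genes))[
    match(gene_of, genes)]
  pos <- as.integer(1e6 * match(gene_of, genes) +
                      100 * (seq_len(m) - 1) %% config$variants_per_gene)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  is_rare <- stats::runif(m) < config$prop_rare
  af <- ifelse(is_rare,
               stats::runif(m, config$rare_af_range[1], config$rare_af_range[2]),
               stats::runif(m, config$common_af_range[1], config$common_af_range[2]))
  is_del <- stats::runif(m) < config$p_deleterious
  sift <- ifelse(is_del, stats::runif(m, 0, 0.05), stats::runif(m, 0.05, 1))
  variants <- data.frame(
    chrom = chrom, pos = pos, ref = unname(ref), alt = unname(alt),
    rsid = sprintf("rs9%07d", seq_len(m)), gene = gene_of,
    sift = round(sift, 4), cadd = round(stats::runif(m, 0, 40), 2),
    ref_af = signif(af, 6), stringsAsFactors = FALSE)
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  validate_variants(variants)
  dosages <- matrix(stats::rbinom(n * m, 2L, rep(af, each = n)),
                    nrow = n, ncol = m,
                    dimnames = list(sprintf("S%05d", seq_len(n)), variants$key))
  list(variants = variants, genotypes = dosages)
}

# Trajectory shape: score_t = baseline * (plateau + (1 - plateau) * exp(-r t)).
sim_trajectory <- function(baseline, plateau, rate, noise_sd) {
  weeks <- HAMD_WEEKS[-1]
  mu <- baseline * (plateau + (1 - plateau) * exp(-rate * weeks))
  score <- round(mu + stats::rnorm(length(weeks), 0, noise_sd))
  pmin(pmax(score, 0), 52)
}

#' Simulate covariates and HAM-D trajectories with planted gene effects
#'
#' The latent liability of *not* responding is
#' `-intercept + sum(effect_g * (1 - GVB_g))` over the configured causal
#' genes (sex-specific effects apply only in the matching stratum), so with
#' zero effects the responder rate is `plogis(intercept)` and positive
#' planted effects lower the remission rate of burden carriers. Responders
#' follow a fast exponential decay to remission-range scores (with an early
#' drop of well over 20%); non-responders split into partial responders
#' (early improvement, non-remitting plateau) and flat non-responders.
#' Missingness is applied only at weeks after week 3.
#'
#' @param config a [sim_config()].
#' @param genotypes,variants output of [simulate_genotypes()].
#' @return phenotype data.frame consumable by [derive_outcomes()].
#' @export
simulate_phenotypes <- function(config, genotypes, variants) {
  set.seed(config$seed * 10L + 2L)
  n <- config$n_samples
  ids <- rownames(genotypes)
  sex <- ifelse(stats::runif(n) < config$prop_male, "male", "female")
  age <- round(pmin(pmax(stats::rnorm(n, 45, 12), 19), 80))
  hads_a <- round(pmin(pmax(stats::rnorm(n, 8, 3), 0), 21))
  baseline <- round(rtruncnorm_lower(n, config$baseline_mean,
                                     config$baseline_sd, config$baseline_min))

  liability <- rep(config$intercept, n)
  if (!is.null(config$causal_genes) && nrow(config$causal_genes) > 0L) {
    gvb <- compute_gvb(genotypes, variants,
                       genes = unique(config$causal_genes$gene))
    for (i in seq_len(nrow(config$causal_genes))) {
      g <- config$causal_genes$gene[i]
      eff <- config$causal_genes$effect[i]
      stratum <- config$causal_genes$stratum[i]
      mask <- if (stratum == "all") rep(1, n) else as.numeric(sex == stratum)
      liability <- liability - eff * (1 - gvb[, g]) * mask
    }
  }
  responder <- stats::runif(n) < stats::plogis(liability)
  partial <- !responder & stats::runif(n) < config$p_partial_nonresponder

  scores <- matrix(NA_integer_, nrow = n, ncol = length(HAMD_WEEKS) - 1L)
  for (i in seq_len(n)) {
    if (responder[i]) {
      plateau <- stats::runif(1, 0.02, 0.22)
      rate <- stats::runif(1, 0.4, 0.8)
    } else if (partial[i]) {
      plateau <- stats::runif(1, 0.45, 0.7)
      rate <- stats::runif(1, 0.5, 1.0)
    } else {
      plateau <- stats::runif(1, 0.85, 1.0)
      rate <- stats::runif(1, 0.2, 0.5)
    }
    scores[i, ] <- sim_trajectory(baseline[i], plateau, rate,
                                  config$score_noise_sd)
  }
  pheno <- data.frame(sample_id = ids, sex = sex, age = age, hads_a = hads_a,
                      hamd_w0 = as.integer(baseline), stringsAsFactors = FALSE)
  late <- HAMD_WEEKS[-1]
  for (j in seq_along(late)) pheno[[paste0("hamd_w", late[j])]] <- scores[, j]

  if (config$missing_rate > 0) {
    set.seed(config$seed * 10L + 3L)
    for (wk in HAMD_WEEKS[HAMD_WEEKS > 3]) {
      col <- paste0("hamd_w", wk)
      drop <- stats::runif(n) < config$missing_rate
      pheno[[col]][drop] <- NA_integer_
    }
  }
  # ground-truth latent class, kept out of the written files
  attr(pheno, "responder") <- responder
  pheno
}

#' Simulate a complete cohort
#'
#' @param config a [sim_config()].
#' @return list with `variants`, `genotypes`, `phenotypes`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  geno <- simulate_genotypes(config)
  pheno <- simulate_phenotypes(config, geno$genotypes, geno$variants)
  list(variants = geno$variants, genotypes = geno$genotypes,
       phenotypes = pheno, config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits the VCF, the flat annotation TSV and the phenotype TSV in the
#' formats read back by [read_annotated_vcf()], [read_annotation_tsv()] and
#' [read_phenotypes()]; the files round-trip exactly.
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             annotations = file.path(dir, "annotations.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  write_annotated_vcf(cohort$variants, cohort$genotypes, paths[["vcf"]])
  write_annotation_tsv(cohort$variants, paths[["annotations"]])
  write_phenotypes(cohort$phenotypes, paths[["phenotypes"]])
  invisible(paths)
}
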