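# Pipeline orchestration: a YAML run configuration, stage functions that
# read/write the TSV interfaces, a JSON run manifest, and a small
# subcommand dispatcher backing the command-line entry point in
# inst/cli/gvburden.

#' Default run configuration
#'
#' A plain named list; unknown keys in a YAML file override these defaults.
#' Paths are resolved relative to the working directory.
#'
#' @param outdir output directory.
#' @param seed master seed for simulation and imputation.
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(outdir = "gvburden_out", seed = 1L) {
  structure(list(
    paths = list(vcf = NULL, annotations = NULL, phenotypes = NULL,
                 gmt = NULL, outdir = outdir),
    gvb = list(sift_deleterious_threshold = 0.7, zero_floor = 0.001,
               per_allele = FALSE, no_variant_score = 1.0),
    rare_set = list(af_threshold = 0.01, af_source = "reference_panel",
                    weight_shape = c(1, 25),
                    rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)),
    imputation = list(n_imputations = 5, max_iter = 10,
                      predictors = c("age", "sex", "hamd_w0", "hads_a")),
    fdr_threshold = 0.25,
    strata = c("total", "male", "female"),
    simulate = list(n_samples = 1000, n_genes = 200, variants_per_gene = 10),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a YAML run configuration
#'
#' Loads a YAML file and merges it over [default_run_config()]; nested keys
#' are merged one level deep.
#'
#' @param path YAML file path.
#' @return merged `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (key in names(user)) {
    if (is.list(cfg[[key]]) && is.list(user[[key]])) {
      for (k2 in names(user[[key]])) cfg[[key]][[k2]] <- user[[key]][[k2]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  cfg
}

cfg_gvb_params <- function(cfg) do.call(gvb_params, cfg$gvb)
cfg_rare_spec <- function(cfg) do.call(rare_set_spec, cfg$rare_set)
cfg_imputation <- function(cfg) {
  do.call(imputation_config, c(cfg$imputation, list(seed = cfg$seed)))
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  dir.create(cfg$paths$outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- list(
    stage = stage,
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "paths")],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = outputs
  )
  path <- file.path(cfg$paths$outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

load_cohort_inputs <- function(cfg) {
  p <- cfg$paths
  if (is.null(p$vcf) || is.null(p$phenotypes))
    stopf("run config must point to 'vcf' and 'phenotypes' inputs")
  vcf <- read_annotated_vcf(p$vcf)
  variants <- if (!is.null(p$annotations)) read_annotation_tsv(p$annotations)
              else vcf$variants
  phenotypes <- read_phenotypes(p$phenotypes)
  genotypes <- vcf$genotypes[phenotypes$sample_id, , drop = FALSE]
  list(variants = variants, genotypes = genotypes, phenotypes = phenotypes)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from the configured paths, writes TSV
#' outputs plus a JSON manifest (input hashes, seed, parameters) under
#' `outdir`, and returns its main result invisibly. `stage_simulate` writes
#' a synthetic cohort; `stage_outcomes` derives pooled outcome labels;
#' `stage_gvb` writes the burden matrix; `stage_associate` runs the
#' two-step association; `stage_enrich` runs over-representation of the
#' candidate genes against a GMT collection; [run_pipeline()] chains them.
#'
#' @param cfg a run configuration list (see [default_run_config()]).
#' @return the stage result, invisibly.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_simulate <- function(cfg) {
  sim <- cfg$simulate
  causal <- if (!is.null(sim$causal_genes)) {
    do.call(rbind, lapply(sim$causal_genes, function(x)
      data.frame(gene = x$gene, effect = x$effect,
                 stratum = x$stratum %||% "all", stringsAsFactors = FALSE)))
  } else NULL
  config <- sim_config(n_samples = sim$n_samples, n_genes = sim$n_genes,
                       variants_per_gene = sim$variants_per_gene,
                       causal_genes = causal, seed = cfg$seed)
  cohort <- simulate_cohort(config)
  dir.create(cfg$paths$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_cohort(cohort, cfg$paths$outdir)
  write_manifest(cfg, "simulate", list(), as.list(paths))
  invisible(cohort)
}

#' @rdname pipeline-stages
#' @export
stage_outcomes <- function(cfg) {
  inputs <- load_cohort_inputs(cfg)
  outcomes <- derive_outcomes(inputs$phenotypes, cfg_imputation(cfg))
  out <- file.path(cfg$paths$outdir, "outcomes.tsv")
  dir.create(cfg$paths$outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(outcomes, out, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  write_manifest(cfg, "outcomes",
                 cfg$paths[c("vcf", "annotations", "phenotypes")],
                 list(outcomes = out))
  invisible(outcomes)
}

#' @rdname pipeline-stages
#' @export
stage_gvb <- function(cfg) {
  inputs <- load_cohort_inputs(cfg)
  gvb <- compute_gvb(inputs$genotypes, inputs$variants, cfg_gvb_params(cfg))
  out <- file.path(cfg$paths$outdir, "gvb_matrix.tsv")
  dir.create(cfg$paths$outdir, showWarnings = FALSE, recursive = TRUE)
  write_gvb_tsv(gvb, out)
  write_manifest(cfg, "gvb", cfg$paths[c("vcf", "annotations")],
                 list(gvb_matrix = out))
  invisible(gvb)
}

#' @rdname pipeline-stages
#' @export
stage_associate <- function(cfg) {
  inputs <- load_cohort_inputs(cfg)
  outcomes <- derive_outcomes(inputs$phenotypes, cfg_imputation(cfg))
  keep <- outcomes$sample_id
  genotypes <- inputs$genotypes[keep, , drop = FALSE]
  gvb <- compute_gvb(genotypes, inputs$variants, cfg_gvb_params(cfg))
  results <- run_two_step(gvb, genotypes, inputs$variants, outcomes,
                          inputs$phenotypes, spec = cfg_rare_spec(cfg),
                          fdr_threshold = cfg$fdr_threshold,
                          strata = cfg$strata)
  paths <- write_association_tsv(results, cfg$paths$outdir)
  write_manifest(cfg, "associate",
                 cfg$paths[c("vcf", "annotations", "phenotypes")],
                 as.list(paths))
  invisible(results)
}

#' @rdname pipeline-stages
#' @param candidates optional candidate gene vector for `stage_enrich`;
#'   defaults to the genes in `outdir/candidates.tsv`.
#' @export
stage_enrich <- function(cfg, candidates = NULL) {
  if (is.null(cfg$paths$gmt)) stopf("run config must point to a 'gmt' file")
  collection <- read_gmt(cfg$paths$gmt)
  if (is.null(candidates)) {
    cand_path <- file.path(cfg$paths$outdir, "candidates.tsv")
    if (!file.exists(cand_path))
      stopf("no candidate list; run stage_associate first or pass candidates")
    candidates <- unique(utils::read.delim(cand_path,
                                           stringsAsFactors = FALSE)$gene)
  }
  res <- ora(candidates, collection)
  out <- file.path(cfg$paths$outdir, "enrichment.tsv")
  utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  write_manifest(cfg, "enrich", cfg$paths["gmt"], list(enrichment = out))
  invisible(res)
}

#' Run the whole pipeline
#'
#' Chains simulation (only when no input VCF is configured), outcome
#' derivation, burden scoring, the two-step association, and (when a GMT
#' collection is configured) over-representation analysis. Identical
#' configuration and seed give identical outputs.
#'
#' @param cfg run configuration list.
#' @return list with `outcomes`, `gvb`, `association`, and `enrichment`
#'   (possibly `NULL`), invisibly.
#' @export
run_pipeline <- function(cfg = default_run_config()) {
  if (is.null(cfg$paths$vcf)) {
    stage_simulate(cfg)
    cfg$paths$vcf <- file.path(cfg$paths$outdir, "cohort.vcf")
    cfg$paths$annotations <- file.path(cfg$paths$outdir, "annotations.tsv")
    cfg$paths$phenotypes <- file.path(cfg$paths$outdir, "phenotypes.tsv")
  }
  outcomes <- stage_outcomes(cfg)
  gvb <- stage_gvb(cfg)
  association <- stage_associate(cfg)
  enrichment <- if (!is.null(cfg$paths$gmt)) {
    stage_enrich(cfg, candidates = unique(association$candidates$gene))
  } else NULL
  invisible(list(outcomes = outcomes, gvb = gvb, association = association,
                 enrichment = enrichment))
}

parse_cli_flags <- function(args) {
  flags <- list()
  positional <- character(0)
  for (a in args) {
    if (startsWith(a, "--")) {
      kv <- sub("^--", "", a)
      if (grepl("=", kv, fixed = TRUE)) {
        parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
        flags[[parts[1]]] <- paste(parts[-1], collapse = "=")
      } else {
        flags[[kv]] <- TRUE
      }
    } else {
      positional <- c(positional, a)
    }
  }
  list(flags = flags, positional = positional)
}

#' Command-line dispatcher
#'
#' Backs the `inst/cli/gvburden` script. Subcommands: `simulate`,
#' `outcomes`, `gvb`, `associate`, `enrich`, `run-all`. Flags:
#' `--config=<yaml>`, `--seed=<int>`, `--outdir=<dir>`, plus
#' `--vcf/--annotations/--phenotypes/--gmt` path overrides. Flags override
#' the configuration file. Logs stage timings to stderr.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit status, invisibly (0 on success).
#' @export
gvb_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- parse_cli_flags(args)
  cmd <- if (length(parsed$positional) >= 1L) parsed$positional[1] else NULL
  usage <- paste("usage: gvburden <simulate|outcomes|gvb|associate|enrich|run-all>",
                 "[--config=FILE] [--seed=N] [--outdir=DIR]",
                 "[--vcf=F] [--annotations=F] [--phenotypes=F] [--gmt=F]")
  if (is.null(cmd) ||
      !cmd %in% c("simulate", "outcomes", "gvb", "associate", "enrich",
                  "run-all")) {
    message(usage)
    return(invisible(1L))
  }
  cfg <- if (!is.null(parsed$flags$config)) read_run_config(parsed$flags$config)
         else default_run_config()
  if (!is.null(parsed$flags$seed)) cfg$seed <- as.integer(parsed$flags$seed)
  if (!is.null(parsed$flags$outdir)) cfg$paths$outdir <- parsed$flags$outdir
  for (p in c("vcf", "annotations", "phenotypes", "gmt")) {
    if (!is.null(parsed$flags[[p]])) cfg$paths[[p]] <- parsed$flags[[p]]
  }
  t0 <- Sys.time()
  status <- tryCatch({
    switch(cmd,
           simulate = stage_simulate(cfg),
           outcomes = stage_outcomes(cfg),
           gvb = stage_gvb(cfg),
           associate = stage_associate(cfg),
           enrich = stage_enrich(cfg),
           `run-all` = run_pipeline(cfg))
    0L
  }, error = function(e) {
    message(sprintf("[gvburden] stage '%s' failed: %s", cmd,
                    conditionMessage(e)))
    1L
  })
  message(sprintf("[gvburden] %s finished in %.1f s (status %d)", cmd,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  status))
  invisible(status)
}
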