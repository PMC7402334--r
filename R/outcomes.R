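# Treatment-outcome derivation from longitudinal HAM-D trajectories:
# inclusion screening, chained-equation imputation of missing follow-up
# scores, early-improvement / remission classification, and pooling of
# labels across imputations.

#' Imputation configuration
#'
#' Settings for the chained-equation imputation of missing HAM-D scores at
#' follow-up visits after week 3.
#'
#' @param n_imputations number of completed datasets (default 5).
#' @param predictors covariate columns used in every imputation model;
#'   defaults to age, sex, baseline HAM-D and baseline HADS-A anxiety score.
#' @param seed RNG seed; each imputation uses an independent substream.
#' @param max_iter chained-equation sweeps per imputation (default 10).
#' @param n_donors donor pool size for predictive mean matching (default 5).
#' @return list of class `imputation_config`.
#' @export
imputation_config <- function(n_imputations = 5,
                              predictors = c("age", "sex", "hamd_w0", "hads_a"),
                              seed = 1L, max_iter = 10L, n_donors = 5L) {
  stopifnot(n_imputations >= 1, max_iter >= 1, n_donors >= 1)
  structure(list(n_imputations = as.integer(n_imputations),
                 predictors = predictors, seed = as.integer(seed),
                 max_iter = as.integer(max_iter),
                 n_donors = as.integer(n_donors)),
            class = "imputation_config")
}

#' Analysis-inclusion check on assessment coverage
#'
#' A record enters the outcome analysis only if the trajectory can anchor
#' both outcome definitions: at least one HAM-D observation within the first
#' two weeks after baseline (week 1 or week 2) AND the week-3 observation.
#'
#' @param phenotypes phenotype data.frame (one or more rows).
#' @return logical vector, one entry per record.
#' @export
check_inclusion <- function(phenotypes) {
  if (any(is.na(phenotypes$hamd_w0)))
    stopf("baseline HAM-D missing; run read_phenotypes() eligibility screen first")
  early <- !is.na(phenotypes$hamd_w1) | !is.na(phenotypes$hamd_w2)
  early & !is.na(phenotypes$hamd_w3)
}

# Design matrix for the imputation models: configured covariates plus the
# current values of every other HAM-D column. sex is coded 0/1.
impute_design <- function(data, predictors, target_col, hamd_columns) {
  covs <- lapply(predictors, function(p) {
    v <- data[[p]]
    if (p == "sex") as.numeric(v == "male") else as.numeric(v)
  })
  names(covs) <- predictors
  others <- setdiff(hamd_columns, c(target_col, "hamd_w0"))
  for (col in others) covs[[col]] <- as.numeric(data[[col]])
  as.matrix(as.data.frame(covs))
}

pmm_draw <- function(y_obs, X_obs, X_mis, n_donors) {
  fit <- stats::lm.fit(cbind(1, X_obs), y_obs)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  pred_obs <- drop(cbind(1, X_obs) %*% beta)
  pred_mis <- drop(cbind(1, X_mis) %*% beta)
  vapply(pred_mis, function(p) {
    d <- abs(pred_obs - p)
    donors <- order(d)[seq_len(min(n_donors, length(d)))]
    y_obs[sample(donors, 1L)]
  }, numeric(1))
}

#' Impute missing follow-up HAM-D scores by chained equations
#'
#' Predictive-mean-matching imputation of HAM-D scores at visits after week
#' 3 (weeks 6, 9, 12). Each incomplete week column is regressed on the
#' configured covariates and the current values of the other HAM-D columns;
#' each missing value receives the observed score of a randomly chosen
#' nearest-prediction donor, so imputations stay on the observed integer
#' support. Values observed in the input are never altered, and scores at
#' weeks 0-3 are never imputed (inclusion requires them or treats them as
#' the early-visit anchor). Imputed scores are clamped to the HAM-D range
#' \[0, 52\] and rounded to integers.
#'
#' @param phenotypes phenotype data.frame; all rows must pass
#'   [check_inclusion()].
#' @param config an [imputation_config()].
#' @return list of `config$n_imputations` completed phenotype data.frames.
#' @export
impute_hamd <- function(phenotypes, config = imputation_config()) {
  if (!all(check_inclusion(phenotypes)))
    stopf("all records must pass check_inclusion() before imputation")
  for (p in config$predictors) {
    if (!p %in% names(phenotypes))
      stopf("imputation predictor '%s' absent from phenotype table", p)
    if (all(is.na(phenotypes[[p]])))
      stopf("imputation predictor '%s' is entirely missing", p)
  }
  imputable <- hamd_cols(HAMD_WEEKS[HAMD_WEEKS > 3])
  incomplete <- imputable[vapply(imputable, function(c) anyNA(phenotypes[[c]]),
                                 logical(1))]
  if (length(incomplete) == 0L)
    return(replicate(config$n_imputations, phenotypes, simplify = FALSE))

  all_hamd <- hamd_cols()
  lapply(seq_len(config$n_imputations), function(i) {
    # independent substream per imputation
    set.seed((config$seed %% 1000000L) * 100L + i)
    data <- phenotypes
    # initialise missing entries with random draws from the observed column
    for (col in incomplete) {
      mis <- is.na(data[[col]])
      obs <- data[[col]][!mis]
      data[[col]][mis] <- sample(obs, sum(mis), replace = TRUE)
    }
    for (sweep in seq_len(config$max_iter)) {
      for (col in incomplete) {
        mis <- is.na(phenotypes[[col]])
        X <- impute_design(data, config$predictors, col, all_hamd)
        y <- data[[col]]
        data[[col]][mis] <- pmm_draw(y[!mis], X[!mis, , drop = FALSE],
                                     X[mis, , drop = FALSE], config$n_donors)
      }
    }
    for (col in incomplete) {
      mis <- is.na(phenotypes[[col]])
      data[[col]][mis] <- pmin(pmax(round(data[[col]][mis]), 0), 52)
    }
    data
  })
}

OUTCOME_GROUPS <- c("ER_neg_REM_neg", "ER_pos_REM_pos", "excluded")

#' Classify treatment outcomes from a completed trajectory
#'
#' Early improvement is a reduction of at least 20% in the HAM-D score at
#' week 2 relative to baseline; remission is a week-12 HAM-D score of at
#' most 7. The 20% boundary is decided by exact integer arithmetic,
#' `(w0 - w2) * 5 >= w0`, so a score pair like 20 -> 16 counts as early
#' improvement with no floating-point ambiguity. The extreme-phenotype
#' group keeps only concordant samples: `ER_neg_REM_neg` (no early
#' improvement, no remission), `ER_pos_REM_pos` (both), everything else
#' `excluded`.
#'
#' @param phenotypes completed phenotype data.frame (weeks 2 and 12 present).
#' @return data.frame with `sample_id`, `early_improvement`, `remission`,
#'   `group`.
#' @export
classify_outcome <- function(phenotypes) {
  w0 <- phenotypes$hamd_w0
  w2 <- phenotypes$hamd_w2
  w12 <- phenotypes$hamd_w12
  if (anyNA(w2) || anyNA(w12))
    stopf("weeks 2 and 12 must be observed or imputed before classification")
  if (any(w0 == 0)) {
    warnf("baseline HAM-D of 0 found; treated as no early improvement")
  }
  early <- w0 > 0 & (w0 - w2) * 5 >= w0
  remission <- w12 <= 7
  group <- ifelse(early & remission, "ER_pos_REM_pos",
                  ifelse(!early & !remission, "ER_neg_REM_neg", "excluded"))
  data.frame(sample_id = phenotypes$sample_id,
             early_improvement = early, remission = remission,
             group = factor(group, levels = OUTCOME_GROUPS),
             stringsAsFactors = FALSE)
}

#' Pool outcome labels across imputations
#'
#' Majority vote per sample on each boolean label; an exact tie takes the
#' label from the first imputation and is flagged. The group is rebuilt from
#' the pooled booleans, keeping the group invariant intact.
#'
#' @param labels_list list of [classify_outcome()] tables over identical
#'   sample sets (one per imputation).
#' @return pooled outcome table with an extra logical `tie` column.
#' @export
pool_outcomes <- function(labels_list) {
  stopifnot(length(labels_list) >= 1)
  ids <- labels_list[[1]]$sample_id
  for (l in labels_list) {
    if (!identical(l$sample_id, ids))
      stopf("all label tables must cover the same samples in the same order")
  }
  m <- length(labels_list)
  vote <- function(field) {
    votes <- rowSums(matrix(vapply(labels_list, function(l) l[[field]],
                                   logical(length(ids))),
                            nrow = length(ids)))
    list(value = ifelse(votes * 2 == m, labels_list[[1]][[field]], votes * 2 > m),
         tie = votes * 2 == m)
  }
  ei <- vote("early_improvement")
  rem <- vote("remission")
  group <- ifelse(ei$value & rem$value, "ER_pos_REM_pos",
                  ifelse(!ei$value & !rem$value, "ER_neg_REM_neg", "excluded"))
  data.frame(sample_id = ids,
             early_improvement = ei$value, remission = rem$value,
             group = factor(group, levels = OUTCOME_GROUPS),
             tie = ei$tie | rem$tie,
             stringsAsFactors = FALSE)
}

#' Derive pooled outcome labels from raw phenotypes
#'
#' Convenience wrapper chaining [check_inclusion()], [impute_hamd()],
#' [classify_outcome()] per imputation, and [pool_outcomes()].
#'
#' @inheritParams impute_hamd
#' @return pooled outcome table (samples failing inclusion are dropped with
#'   a warning).
#' @export
derive_outcomes <- function(phenotypes, config = imputation_config()) {
  keep <- check_inclusion(phenotypes)
  if (any(!keep)) {
    warnf("dropping %d record(s) without the required week-1/2 and week-3 assessments",
          sum(!keep))
    phenotypes <- phenotypes[keep, , drop = FALSE]
  }
  completed <- impute_hamd(phenotypes, config)
  pool_outcomes(lapply(completed, classify_outcome))
}
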