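# Optimal sequence kernel association test (SKAT-O) for binary traits.
#
# The statistic family Q_rho = (1 - rho) * sum_j S_j^2 + rho * (sum_j S_j)^2
# interpolates between the variance-component SKAT statistic (rho = 0) and
# the squared weighted burden score (rho = 1), where S = W G' (y - mu) is
# the weighted score vector from a null logistic model on covariates only.
# Each Q_rho is a quadratic form in asymptotically normal scores, so its
# null tail is a mixture of 1-df chi-squares; the optimal test takes the
# minimum p over a rho grid and corrects it with the one-dimensional
# integral of Lee et al., decomposing Q_rho into a common burden-direction
# chi-square and a residual mixture.

#' Rare-variant set specification for SKAT-O
#'
#' @param af_threshold variants with allele frequency strictly below this
#'   enter the rare set (default 0.01).
#' @param af_source `"reference_panel"` uses the annotated `ref_af`
#'   (1000-Genomes role), falling back to cohort frequency where missing;
#'   `"cohort"` always uses the cohort allele frequency.
#' @param weight_shape Beta density shape parameters applied to the minor
#'   allele frequency to weight variants (default `c(1, 25)`, up-weighting
#'   the rarest variants).
#' @param rho_grid grid of burden/kernel correlation values searched by the
#'   optimal test; must lie in \[0, 1\] and contain 0 and 1.
#' @return list of class `rare_set_spec`.
#' @export
rare_set_spec <- function(af_threshold = 0.01,
                          af_source = c("reference_panel", "cohort"),
                          weight_shape = c(1, 25),
                          rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)) {
  af_source <- match.arg(af_source)
  if (!(af_threshold > 0 && af_threshold < 0.5))
    stopf("af_threshold must lie in (0, 0.5)")
  if (any(rho_grid < 0 | rho_grid > 1) || !0 %in% rho_grid || !1 %in% rho_grid)
    stopf("rho_grid must lie in [0,1] and contain 0 and 1")
  structure(list(af_threshold = af_threshold, af_source = af_source,
                 weight_shape = weight_shape, rho_grid = sort(rho_grid)),
            class = "rare_set_spec")
}

# Null logistic model pieces shared across genes: fitted probabilities and
# the projection needed for score covariance under the null.
skat_null_model <- function(y, covariates = NULL) {
  if (!is_binary01(y)) stopf("outcome must be coded 0/1")
  X <- if (is.null(covariates) || NCOL(covariates) == 0L) {
    matrix(1, nrow = length(y), ncol = 1L)
  } else {
    cbind(1, as.matrix(covariates))
  }
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  mu <- fit$fitted.values
  list(y = y, X = X, mu = mu, resid = y - mu, d = mu * (1 - mu))
}

# Score vector and its null covariance for a weighted genotype block.
# A = Gw' P Gw with P = D - D X (X' D X)^{-1} X' D.
skat_score_pieces <- function(G, weights, null) {
  Gw <- sweep(G, 2L, weights, `*`)
  S <- drop(crossprod(Gw, null$resid))
  dGw <- Gw * null$d
  XtDX <- crossprod(null$X * null$d, null$X)
  B <- crossprod(null$X, dGw)                       # p x m
  A <- crossprod(Gw, dGw) - crossprod(B, solve(XtDX, B))
  list(S = S, A = A, Gw = Gw)
}

# Symmetric square root of R_rho = (1-rho) I + rho J (m x m).
rho_matrix_sqrt <- function(rho, m) {
  a <- sqrt(1 - rho)
  b <- (sqrt(1 - rho + m * rho) - a) / m
  diag(a, m) + matrix(b, m, m)
}

# Eigenvalues of R_rho^{1/2} A R_rho^{1/2} (null mixture weights of Q_rho).
q_rho_lambdas <- function(A, rho) {
  m <- nrow(A)
  Rh <- rho_matrix_sqrt(rho, m)
  lam <- eigen(Rh %*% A %*% Rh, symmetric = TRUE, only.values = TRUE)$values
  lam[lam > max(lam) * 1e-10]
}

# Lee et al. mixture parameters for the SKAT-O combination integral,
# derived purely from the score covariance A.
skato_optimal_params <- function(A, rho_grid) {
  m <- nrow(A)
  a1 <- drop(A %*% rep(1, m))
  s2 <- sum(a1) / m^2                 # z-bar' z-bar
  if (s2 <= 0) return(NULL)
  cof <- a1 / (m * s2)                # projections of columns on burden dir
  A2 <- A - s2 * tcrossprod(cof)      # residual (I - M) component
  lambda <- eigen(A2, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > sum(diag(A)) * 1e-10]
  var_zeta <- 4 * s2 * drop(crossprod(cof, A2 %*% cof))
  tau <- m^2 * rho_grid * s2 + (1 - rho_grid) * s2 * sum(cof^2)
  list(lambda = lambda, mu_q = sum(lambda),
       var_q = 2 * sum(lambda^2) + var_zeta, var_zeta = var_zeta, tau = tau)
}

# SKAT-O p-value for given score pieces; exported wrapper below handles the
# rare-set plumbing.
skato_pvalue <- function(S, A, rho_grid) {
  m <- length(S)
  sum_s <- sum(S)
  ssq <- sum(S^2)
  Q <- (1 - rho_grid) * ssq + rho_grid * sum_s^2
  lam_list <- lapply(rho_grid, function(r) q_rho_lambdas(A, r))
  p_rho <- vapply(seq_along(rho_grid), function(i) {
    as.numeric(mixture_chisq_sf(Q[i], lam_list[[i]]))
  }, numeric(1))
  if (length(rho_grid) == 1L) {
    return(list(p = p_rho, rho_min = rho_grid, p_rho = p_rho,
                Q = Q, method = "single_rho"))
  }
  T_min <- min(p_rho)
  par <- skato_optimal_params(A, rho_grid)
  if (length(S) == 1L || (!is.null(par) && length(par$lambda) == 0L)) {
    # single variant or fully correlated set: every Q_rho is the same
    # burden chi-square, so the minimum component p IS the p-value
    return(list(p = T_min, rho_min = rho_grid[which.min(p_rho)],
                p_rho = p_rho, Q = Q, method = "burden_equivalent"))
  }
  if (is.null(par) || T_min <= 0) {
    return(list(p = min(1, T_min * length(rho_grid)),
                rho_min = rho_grid[which.min(p_rho)], p_rho = p_rho,
                Q = Q, method = "bonferroni"))
  }
  # per-rho statistic thresholds at the observed minimum p
  q_min <- vapply(seq_along(rho_grid), function(i) {
    liu_quantile(T_min, lam_list[[i]])
  }, numeric(1))
  rho_eff <- pmin(rho_grid, 0.999)    # rho = 1 handled in the limit
  sd_ratio <- sqrt((par$var_q - par$var_zeta) / par$var_q)
  kappa_sf <- mixture_chisq_sf_factory(par$lambda, tol = 1e-6)$sf
  a_terms <- q_min / (1 - rho_eff)
  b_terms <- par$tau / (1 - rho_eff)
  integrand <- function(x) {
    bound <- do.call(pmin, lapply(seq_along(a_terms),
                                  function(i) a_terms[i] - b_terms[i] * x))
    bound_adj <- (bound - par$mu_q) * sd_ratio + par$mu_q
    ok <- bound > 0 & bound_adj > 0
    out <- numeric(length(x))
    if (any(ok))
      out[ok] <- (1 - kappa_sf(bound_adj[ok])) * stats::dchisq(x[ok], df = 1)
    out
  }
  # the integrand vanishes once any per-rho threshold is exceeded
  x_upper <- min(q_min / par$tau, 40)
  int <- tryCatch(
    stats::integrate(integrand, 0, x_upper, subdivisions = 1000L,
                     rel.tol = 1e-6, stop.on.error = FALSE),
    error = function(e) NULL)
  p <- if (is.null(int)) NA_real_ else 1 - int$value
  # numerical guardrails: the optimal p cannot beat the minimum component p
  # and cannot exceed its Bonferroni bound
  if (!is.finite(p)) p <- min(1, T_min * length(rho_grid))
  p <- min(max(p, T_min), T_min * length(rho_grid), 1)
  list(p = p, rho_min = rho_grid[which.min(p_rho)], p_rho = p_rho, Q = Q,
       method = "integral")
}

#' SKAT-O test on a rare-variant genotype block
#'
#' Binary-trait score-based optimal kernel association test. A null
#' logistic model with covariates only provides the residuals; variants are
#' weighted by `dbeta(MAF, shape1, shape2)`; the statistic is minimised in
#' p over the rho grid and corrected by the one-dimensional mixture
#' integral. Missing dosages are treated as homozygous reference.
#'
#' @param geno samples x variants dosage matrix for the (already
#'   rare-filtered) variant set of one gene.
#' @param outcome 0/1 vector (1 = the modelled class).
#' @param covariates optional numeric matrix/data.frame of adjustment
#'   covariates.
#' @param spec a [rare_set_spec()] (weights and rho grid).
#' @param maf optional per-variant minor allele frequencies used for the
#'   weights; defaults to cohort frequencies computed from `geno`.
#' @param null_model optional prefitted null model (internal
#'   `skat_null_model()` result) so the covariate-only logistic fit can be
#'   shared across the genes of one stratum.
#' @return list with `p` (final p-value in (0, 1\]), `p_rho` (per-rho
#'   component p-values), `rho_min`, `Q` (per-rho statistics), `n_variants`
#'   and `method` (`"integral"`, `"single_rho"`, or `"bonferroni"` /
#'   `"degenerate"` fallbacks).
#' @export
skat_o <- function(geno, outcome, covariates = NULL, spec = rare_set_spec(),
                   maf = NULL, null_model = NULL) {
  geno <- as.matrix(geno)
  if (anyNA(geno)) geno[is.na(geno)] <- 0
  keep <- apply(geno, 2L, function(g) stats::var(g) > 0)
  if (!any(keep))
    return(list(p = NA_real_, p_rho = NA_real_, rho_min = NA_real_,
                Q = NA_real_, n_variants = 0L, method = "degenerate"))
  if (!is.null(maf)) maf <- maf[keep]
  geno <- geno[, keep, drop = FALSE]
  if (is.null(maf)) maf <- colMeans(geno) / 2
  maf <- pmin(pmax(maf, 1e-6), 1 - 1e-6)
  maf <- pmin(maf, 1 - maf)
  w <- stats::dbeta(maf, spec$weight_shape[1], spec$weight_shape[2])
  null <- null_model %||% skat_null_model(outcome, covariates)
  pieces <- skat_score_pieces(geno, w, null)
  res <- skato_pvalue(pieces$S, pieces$A, spec$rho_grid)
  res$n_variants <- ncol(geno)
  res
}

#' Weighted burden score test (the rho = 1 limit of SKAT-O)
#'
#' Convenience wrapper: `skat_o` with `rho_grid = 1`, i.e. a score test on
#' the weighted sum of dosages.
#'
#' @inheritParams skat_o
#' @return list as for [skat_o()].
#' @export
burden_test <- function(geno, outcome, covariates = NULL,
                        spec = rare_set_spec(), maf = NULL) {
  spec$rho_grid <- 1
  res <- skat_o(geno, outcome, covariates, spec, maf)
  res
}
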