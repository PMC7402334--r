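# Upper-tail probability of a positively weighted sum of independent 1-df
# chi-square variables, Q = sum_i lambda_i * chisq_1 — the null
# distribution of variance-component score statistics (SKAT and the
# per-rho statistics inside SKAT-O).
#
# Primary route: Ruben's expansion of the distribution as an infinite
# mixture of central chi-square distributions, whose truncation error is
# provably bounded by the mixture mass not yet accumulated. Secondary
# route: numerical inversion of the characteristic function (Imhof's
# integral). Last resort: the Liu et al. moment-matching non-central
# chi-square approximation (kurtosis-matched variant), flagged in the
# result.

# Liu et al. moment-matching parameters (kurtosis-matched variant).
liu_params <- function(lambdas) {
  c1 <- sum(lambdas); c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3); c4 <- sum(lambdas^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), l = l, delta = delta,
       muX = l + delta, sigmaX = sqrt(2 * (l + 2 * delta)))
}

liu_sf <- function(q, lambdas) {
  p <- liu_params(lambdas)
  tstar <- (q - p$muQ) / p$sigmaQ
  stats::pchisq(tstar * p$sigmaX + p$muX, df = p$l, ncp = p$delta,
                lower.tail = FALSE)
}

# Upper-tail quantile of the mixture under the Liu approximation.
liu_quantile <- function(p_upper, lambdas) {
  par <- liu_params(lambdas)
  q_chi <- stats::qchisq(p_upper, df = par$l, ncp = par$delta,
                         lower.tail = FALSE)
  (q_chi - par$muX) / par$sigmaX * par$sigmaQ + par$muQ
}

# Ruben (1962) expansion: with beta = min(lambda),
#   P(Q > q) = sum_{k>=0} c_k P(chisq_{m + 2k} > q / beta),
# where the non-negative c_k sum to 1 and are the power-series
# coefficients of f(z) = prod_i (1 - b_i z)^{-1/2} at b_i = 1 -
# beta/lambda_i, scaled by c_0 = prod(beta/lambda)^{1/2}. The
# coefficients satisfy the linear recurrence induced by the ODE
# P(z) f'(z) = R(z) f(z) with P(z) = prod(1 - b_i z) and R = -P'/2,
# which costs O(K m) for K terms. Truncation after K terms
# underestimates the tail by at most 1 - sum_{k<=K} c_k.
ruben_coef <- function(lambdas, tol = 1e-9, max_terms = 32768L) {
  # negligible eigenvalues blow up the series length (convergence is
  # geometric with rate 1 - min/max); dropping a trailing set whose total
  # mass is far below the distribution scale perturbs the tail probability
  # by less than ~1e-4 while keeping the expansion short
  lambdas <- sort(lambdas, decreasing = TRUE)
  scale_sd <- sqrt(2 * sum(lambdas^2))
  cum_tail <- rev(cumsum(rev(lambdas)))
  keep <- cum_tail > 1e-4 * scale_sd
  if (!keep[1]) keep[1] <- TRUE
  lambdas <- lambdas[keep]
  m <- length(lambdas)
  beta <- min(lambdas)
  b <- 1 - beta / lambdas
  b <- b[b > 1e-14]
  c0 <- exp(0.5 * sum(log(beta / lambdas)))
  if (length(b) == 0L)
    return(list(beta = beta, m = m, cf = c0, remainder = 0))
  # pre-check: geometric decay rate max(b); skip if convergence is hopeless
  k_est <- log(tol / 10) / log(max(b))
  if (!is.finite(k_est) || k_est > max_terms)
    return(list(beta = beta, m = m, cf = c0, remainder = 1 - c0))
  # polynomial P(z) = prod (1 - b_i z); R = -P'/2
  P <- 1
  for (bi in b) P <- c(P, 0) - c(0, P * bi)
  deg <- length(P) - 1L
  R <- -0.5 * P[-1] * seq_len(deg)
  K <- max(256L, 2L * as.integer(ceiling(k_est)))
  K <- min(K, max_terms)
  cf <- .ruben_coef_rec(P, R, c0, K)
  cf[cf < 0] <- 0            # guard tiny negative round-off
  csum <- cumsum(cf)
  k_use <- which(csum >= 1 - tol)[1]
  if (is.na(k_use)) k_use <- K + 1L
  cf <- cf[seq_len(k_use)]
  # tail mass sum_{k > j} c_k, used by the ladder evaluation below
  tails <- sum(cf) - cumsum(cf)[-length(cf)]
  list(beta = beta, m = m, cf = cf, tails = tails,
       remainder = max(0, 1 - csum[k_use]))
}

ruben_sf_eval <- function(q, coef) {
  # sum_k c_k P(chisq_{m+2k} > q/beta) via the survival-function ladder
  # S_{df+2}(u) = S_df(u) + u^{df/2} e^{-u/2} / (2^{df/2} Gamma(df/2 + 1)).
  # Exchanging sums, P(Q > q) = S_m(u) * sum(c) + sum_j incr_j(u) * T_j with
  # tail masses T_j = sum_{k > j} c_k, which vectorises over q.
  m <- coef$m
  K <- length(coef$cf)
  u <- pmax(q, 0) / coef$beta
  base <- stats::pchisq(u, df = m, lower.tail = FALSE) * sum(coef$cf)
  if (K == 1L) return(base)
  halfdf <- 0.5 * m + (seq_len(K - 1L) - 1L)
  logconst <- -halfdf * log(2) - lgamma(halfdf + 1)
  L <- outer(halfdf, log(u)) + logconst
  L <- sweep(L, 2L, 0.5 * u, `-`)
  base + drop(crossprod(exp(L), coef$tails))
}

imhof_sf <- function(q, lambdas) {
  # P(Q > q) = 1/2 + (1/pi) * Int_0^inf sin(theta(u)) / (u * rho(u)) du
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambdas, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambdas^2, u^2))))
    val <- sin(theta) / (u * rho)
    val[u == 0] <- 0.5 * (sum(lambdas) - q)   # limit as u -> 0
    val
  }
  res <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-12,
                          subdivisions = 500L, stop.on.error = FALSE)
  list(p = 0.5 + res$value / pi, abs_error = res$abs.error / pi,
       message = res$message)
}

# Factory: precompute what is reusable for a fixed lambda set and return a
# vectorized survival function plus the method label. Used heavily inside
# the SKAT-O combination integral.
mixture_chisq_sf_factory <- function(lambdas, tol = 1e-8) {
  lambdas <- lambdas[lambdas > max(lambdas, 0) * 1e-12 & lambdas > 0]
  if (length(lambdas) == 0L) stopf("lambdas must contain a positive weight")
  if (length(lambdas) == 1L) {
    lam <- lambdas
    return(list(sf = function(q) stats::pchisq(pmax(q, 0) / lam, df = 1,
                                               lower.tail = FALSE),
                method = "exact"))
  }
  coef <- ruben_coef(lambdas, tol = tol / 10)
  if (coef$remainder < tol) {
    return(list(sf = function(q) {
      out <- ruben_sf_eval(pmax(q, 0), coef)
      pmin(pmax(out, 0), 1)
    }, method = "ruben"))
  }
  # characteristic-function inversion with a permanent switch to the Liu
  # approximation after the first non-convergent inversion (repeating a
  # failing quadrature at every evaluation would be wasted work)
  imhof_ok <- TRUE
  list(sf = function(q) {
    vapply(q, function(qi) {
      if (qi <= 0) return(1)
      if (imhof_ok) {
        im <- tryCatch(imhof_sf(qi, lambdas), error = function(e) NULL)
        if (!is.null(im) && im$message == "OK" && im$abs_error < tol &&
            im$p > im$abs_error && im$p <= 1 + tol)
          return(min(max(im$p, 0), 1))
        imhof_ok <<- FALSE
      }
      min(max(liu_sf(qi, lambdas), 0), 1)
    }, numeric(1))
  }, method = "imhof_liu")
}

#' Survival function of a weighted sum of 1-df chi-squares
#'
#' Computes `P(sum_i lambda_i * X_i > q)` for independent `X_i ~ chisq(1)`.
#' The primary method is Ruben's central chi-square mixture expansion,
#' whose truncation error is bounded by the mixture mass not yet
#' accumulated; when that bound cannot be met (extreme eigenvalue spread),
#' numerical characteristic-function inversion (Imhof's integral) is
#' tried, and finally the Liu moment-matching approximation. The method
#' actually used is recorded in the `"method"` attribute.
#'
#' @param q statistic value (scalar); `q <= 0` returns 1.
#' @param lambdas non-negative eigenvalue weights, not all zero (zeros and
#'   negligible values below `max(lambdas) * 1e-12` are dropped).
#' @param tol acceptable absolute error (default 1e-8).
#' @return upper-tail probability in \[0, 1\] with attribute `method`
#'   (`"exact"`, `"ruben"`, `"imhof"` or `"liu"`).
#' @export
mixture_chisq_sf <- function(q, lambdas, tol = 1e-8) {
  lambdas <- lambdas[lambdas > max(lambdas, 0) * 1e-12 & lambdas > 0]
  if (length(lambdas) == 0L) stopf("lambdas must contain a positive weight")
  if (q <= 0) return(structure(1, method = "exact"))
  if (length(lambdas) == 1L)
    return(structure(stats::pchisq(q / lambdas, df = 1, lower.tail = FALSE),
                     method = "exact"))
  coef <- ruben_coef(lambdas, tol = tol / 10)
  if (coef$remainder < tol) {
    p <- ruben_sf_eval(q, coef)
    return(structure(min(max(p, 0), 1), method = "ruben"))
  }
  im <- tryCatch(imhof_sf(q, lambdas), error = function(e) NULL)
  if (!is.null(im) && im$message == "OK" && im$abs_error < tol &&
      im$p > im$abs_error && im$p <= 1 + tol)
    return(structure(min(max(im$p, 0), 1), method = "imhof"))
  structure(min(max(liu_sf(q, lambdas), 0), 1), method = "liu")
}

# Upper-tail quantile by root-finding on mixture_chisq_sf.
mixture_chisq_quantile <- function(p_upper, lambdas, tol = 1e-10) {
  lambdas <- lambdas[lambdas > 0]
  upper <- sum(lambdas) * 2 + 10 * sqrt(2 * sum(lambdas^2))
  while (mixture_chisq_sf(upper, lambdas) > p_upper) upper <- upper * 2
  stats::uniroot(function(q) mixture_chisq_sf(q, lambdas) - p_upper,
                 lower = 0, upper = upper, tol = tol)$root
}
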