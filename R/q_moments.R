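#' Cochran's Q statistic with tau-squared-adjusted weights
#'
#' Computes \eqn{Q(\tau^2) = \sum_i w_i(\tau^2)(\hat\theta_i - \bar\theta_w)^2}
#' with inverse-variance weights \eqn{w_i(\tau^2) = 1/(v_i^2 + \tau^2)} and
#' the weighted mean taken with the same weights.  `tau2 = 0` gives the
#' classical heterogeneity statistic.  As a function of `tau2` the statistic
#' is continuous, nonincreasing and convex, which the profile-type interval
#' estimators exploit.
#'
#' @param records An [effect_records()] data frame with at least two studies.
#' @param tau2 Nonnegative heterogeneity variance at which to evaluate Q.
#' @return The value of the statistic (nonnegative scalar).
#' @export
#' @examples
#' r <- effect_records(c(0.2, 0.5, 0.9), c(0.04, 0.05, 0.06),
#'                     c(25, 30, 40), c(25, 28, 40), "SMD")
#' cochran_q(r, 0)
#' cochran_q(r, 0.1)
cochran_q <- function(records, tau2 = 0) {
  check_records(records, caller = "cochran_q")
  if (!is.finite(tau2) || tau2 < 0) stop("'tau2' must be >= 0", call. = FALSE)
  w <- 1 / (records$variance + tau2)
  ybar <- sum(w * records$estimate) / sum(w)
  sum(w * (records$estimate - ybar)^2)
}

# generalized Q with arbitrary positive constants a_i (Jackson's family)
gen_q <- function(records, a) {
  ybar <- sum(a * records$estimate) / sum(a)
  sum(a * (records$estimate - ybar)^2)
}

#' Welch-type correction terms for mean-difference meta-analysis
#'
#' Computes the per-study terms entering the corrected null moments of Q
#' for MD:
#' \deqn{\gamma_i = \frac{\hat\sigma_{iT}^4}{n_{iT}^2 f_{iT}} +
#'                  \frac{\hat\sigma_{iC}^4}{n_{iC}^2 f_{iC}},\qquad
#'       f_{ij} = n_{ij} - 1,}
#' together with the weights \eqn{w_i(\tau^2)} and
#' \eqn{p_i = 1 - w_i / W}.  The estimated arm variances stand in for the
#' true ones.  \eqn{\gamma_i} is half the variance of the estimated
#' within-study variance \eqn{v_i^2}, which is what makes the estimated
#' inverse-variance weights random.
#'
#' @param records MD [effect_records()] with per-arm standard deviations.
#' @param tau2 Heterogeneity value at which the weights are evaluated.
#' @return An object of class `"gamma_terms"`: list with `gamma` (per-study
#'   \eqn{\gamma_i}), `w`, `p`, `W` and `K`.
#' @export
welch_gamma_terms <- function(records, tau2 = 0) {
  check_records(records, min_k = 1L, measure = "MD", need_arm_sd = TRUE,
                caller = "welch_gamma_terms")
  fT <- records$n_treat - 1
  fC <- records$n_control - 1
  gam <- records$sd_treat^4 / (records$n_treat^2 * fT) +
    records$sd_control^4 / (records$n_control^2 * fC)
  w <- 1 / (records$variance + tau2)
  W <- sum(w)
  structure(list(gamma = gam, w = w, p = 1 - w / W, W = W, K = nrow(records)),
            class = "gamma_terms")
}

#' Corrected null moments of Q for mean difference (Welch approximation)
#'
#' First two moments of the classical Q statistic under homogeneity,
#' corrected for the randomness of the estimated weights:
#' \deqn{\kappa_1 = K - 1 + 2\sum_i w_i^2\gamma_i p_i^2,\qquad
#'       \kappa_2 = 2(K - 1) + 14\sum_i w_i^2\gamma_i p_i^2.}
#' The null distribution of Q is then approximated by a scaled F
#' distribution \eqn{\hat c F_{K-1,\hat f_2}} whose first two moments match
#' \eqn{(\kappa_1, \kappa_2)}; see [match_scaled_f()].  The corrections
#' vanish (and the classical \eqn{\chi^2_{K-1}} limit is recovered) when
#' every \eqn{\gamma_i \to 0}, i.e. for large arms.
#'
#' @param terms A [welch_gamma_terms()] object.
#' @return An object of class `"q_moments"`: list with `kappa1`, `kappa2`,
#'   `scale_c`, `df2`, `family` (`"SCALED_F"`, or `"CHISQ_MOMENT"` if no
#'   valid F match exists) and `correction` (the common summand).
#' @export
welch_null_moments <- function(terms) {
  stopifnot(inherits(terms, "gamma_terms"))
  K <- terms$K
  S <- sum(terms$w^2 * terms$gamma * terms$p^2)
  kappa1 <- K - 1 + 2 * S
  kappa2 <- 2 * (K - 1) + 14 * S
  fit <- match_scaled_f(kappa1, kappa2, K)
  structure(list(kappa1 = kappa1, kappa2 = kappa2,
                 scale_c = fit$scale_c, df2 = fit$df2, family = fit$family,
                 correction = S),
            class = "q_moments")
}

#' Moment-match a scaled F distribution
#'
#' Finds \eqn{(c, f_2)} such that \eqn{c F_{K-1, f_2}} has mean `kappa1`
#' and variance `kappa2`, using the closed-form solution of the two moment
#' equations.  A finite variance requires \eqn{f_2 > 4}; when the moments
#' admit no such solution the fit falls back to a chi-squared distribution
#' with `kappa1` degrees of freedom (first-moment matching only) and the
#' returned `family` flags this.
#'
#' @param kappa1,kappa2 Target mean and variance (both positive).
#' @param K Number of studies; the numerator degrees of freedom are `K - 1`.
#' @return List with `scale_c`, `df2` and `family`.
#' @export
#' @examples
#' fit <- match_scaled_f(9.3, 19.1, 10)
#' c(fit$scale_c * fit$df2 / (fit$df2 - 2), 9.3)  # mean reproduced
match_scaled_f <- function(kappa1, kappa2, K) {
  stopifnot(kappa1 > 0, kappa2 > 0, K >= 2)
  k1 <- K - 1
  # E[cF] = c f2/(f2-2);  Var[cF] = 2 c^2 f2^2 (k1 + f2 - 2) / (k1 (f2-2)^2 (f2-4))
  # ratio kappa2/kappa1^2 = 2(k1+f2-2)/(k1(f2-4)) is free of c: solve for f2.
  den <- kappa2 * k1 - 2 * kappa1^2
  if (den > 0) {
    f2 <- (4 * kappa2 * k1 + 2 * kappa1^2 * (k1 - 2)) / den
    if (is.finite(f2) && f2 > 4) {
      c0 <- kappa1 * (f2 - 2) / f2
      return(list(scale_c = c0, df2 = f2, family = "SCALED_F"))
    }
  }
  list(scale_c = NA_real_, df2 = NA_real_, family = "CHISQ_MOMENT")
}

# quantile of the matched null approximation for the WT profile
wt_null_quantile <- function(p, moments, K) {
  if (moments$family == "SCALED_F")
    moments$scale_c * stats::qf(p, K - 1, moments$df2)
  else
    stats::qchisq(p, df = moments$kappa1)
}

## ------------------------------------------------------------------
## Corrected expected value of Q for SMD
## ------------------------------------------------------------------

# Gauss nodes are cached per (n, precision) since they are reused heavily
# across root-finding iterations.
.quad_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n, lo, hi) {
  key <- sprintf("gl%d", n)
  base <- .quad_cache[[key]]
  if (is.null(base)) {
    base <- pracma::gaussLegendre(n, -1, 1)
    .quad_cache[[key]] <- base
  }
  list(x = (hi + lo) / 2 + (hi - lo) / 2 * base$x,
       w = (hi - lo) / 2 * base$w)
}

gauss_hermite <- function(n) {
  key <- sprintf("gh%d", n)
  gh <- .quad_cache[[key]]
  if (is.null(gh)) {
    gh <- pracma::gaussHermite(n)
    .quad_cache[[key]] <- gh
  }
  gh
}

# Per-study quadrature grid for the sampling distribution of Hedges's g:
# g = J(m) T / sqrt(ntilde) with T noncentral t on m df (ncp sqrt(ntilde) d).
# Under heterogeneity the study effect d is integrated over N(delta, tau2)
# (Gauss-Hermite).  Returns the flattened grid: integration weight `wt`,
# value of the record's weight function `w`, and centered effect `u`.
smd_study_grid <- function(n_treat, n_control, b, delta, tau2,
                           n_gl = 160L, n_gh = 24L) {
  n <- n_treat + n_control
  m <- n - 2
  ntil <- n_treat * n_control / n
  J <- hedges_j(m)
  a <- 1 / ntil
  if (tau2 > 0) {
    gh <- gauss_hermite(n_gh)
    dels <- delta + sqrt(2 * tau2) * gh$x
    wd <- gh$w / sqrt(pi)
  } else {
    dels <- delta
    wd <- 1
  }
  wt <- numeric(0); gg <- numeric(0)
  for (j in seq_along(dels)) {
    lam <- sqrt(ntil) * dels[j]
    lo <- suppressWarnings(stats::qt(1e-9, m, lam))
    hi <- suppressWarnings(stats::qt(1 - 1e-9, m, lam))
    gl <- gauss_legendre(n_gl, lo, hi)
    wt <- c(wt, wd[j] * gl$w * suppressWarnings(stats::dt(gl$x, m, lam)))
    gg <- c(gg, J * gl$x / sqrt(ntil))
  }
  list(wt = wt, w = 1 / (a + b * gg^2 + tau2), u = gg - delta)
}

# quadratic coefficient of the record's variance model v^2 = 1/ntilde + b g^2,
# inferred from the record itself; conventional 1/(2n) fallback when the
# estimate is too close to zero to identify b.
smd_var_coef <- function(records) {
  n <- records$n_treat + records$n_control
  ntil <- records$n_treat * records$n_control / n
  b <- (records$variance - 1 / ntil) / records$estimate^2
  bad <- !is.finite(b) | b <= 0 | abs(records$estimate) < 1e-4
  b[bad] <- 1 / (2 * n[bad])
  b
}

#' Corrected expected value of Q for standardized mean difference
#'
#' Expected value of the heterogeneity statistic \eqn{Q(\tau^2)} under the
#' random-effects model in which Hedges's \eqn{g_i} follows its exact
#' scaled noncentral t distribution and the study effects are
#' \eqn{N(\delta, \tau^2)}.  Because each record's estimated variance is a
#' deterministic function of its own \eqn{g_i}, the estimated weights are
#' random, and the expectation falls below the classical \eqn{K - 1}; the
#' corrected-moment point and interval estimators for SMD equate
#' \eqn{Q(\tau^2)} to this value rather than to \eqn{K - 1}.
#'
#' Single-study expectations are computed by Gauss-Legendre quadrature on
#' the noncentral t density (Gauss-Hermite over the random effect when
#' `tau2 > 0`), so they carry no series truncation; the only approximation
#' is in the weighted-mean cross term, evaluated by a third-order delta
#' expansion (`ratio = "moment"`, default) or by an exact
#' Laplace-transform integral (`ratio = "laplace"`).  The two agree to
#' about 1e-5 on typical problems and are cross-checked in the unit tests.
#'
#' @param records SMD [effect_records()].
#' @param delta Common true effect (plug in an estimate in practice).
#' @param tau2 Heterogeneity variance at which Q's weights are taken and
#'   over which the study effects are mixed.
#' @param ratio Evaluation method for the cross term.
#' @return An object of class `"q_moments"` with family `"CHISQ_MOMENT"`;
#'   `kappa1` holds the corrected expectation, which is also the degrees of
#'   freedom of the approximating chi-squared distribution.
#' @export
kdb_expected_q <- function(records, delta, tau2 = 0,
                           ratio = c("moment", "laplace")) {
  check_records(records, measure = "SMD", caller = "kdb_expected_q")
  ratio <- match.arg(ratio)
  n <- records$n_treat + records$n_control
  if (any(n < 8))
    warning("very small studies (n < 8): the noncentral-t moment ",
            "corrections are numerically delicate")
  b <- smd_var_coef(records)
  K <- nrow(records)
  G <- lapply(seq_len(K), function(i)
    smd_study_grid(records$n_treat[i], records$n_control[i], b[i],
                   delta, tau2))
  EA <- sum(vapply(G, function(g) sum(g$wt * g$w * g$u^2), 0))
  EB <- if (ratio == "moment") kdb_ratio_moment(G) else kdb_ratio_laplace(G)
  kappa1 <- EA - EB
  structure(list(kappa1 = kappa1, kappa2 = NA_real_,
                 scale_c = NA_real_, df2 = kappa1, family = "CHISQ_MOMENT",
                 correction = kappa1 - (K - 1)),
            class = "q_moments")
}

# E[U^2/V], U = sum w_i u_i, V = sum w_i, via third-order delta expansion
# around the means; per-study raw cross moments are exact quadratures.
kdb_ratio_moment <- function(G) {
  mom <- function(g, f) sum(g$wt * f)
  u0 <- 0; v0 <- 0
  varU <- 0; covUV <- 0; varV <- 0
  dU2dV <- 0; dUdV2 <- 0; dV3 <- 0
  for (g in G) {
    Ewu   <- mom(g, g$w * g$u);       Ew   <- mom(g, g$w)
    Ew2u2 <- mom(g, g$w^2 * g$u^2);   Ew2  <- mom(g, g$w^2)
    Ew2u  <- mom(g, g$w^2 * g$u)
    Ew3u2 <- mom(g, g$w^3 * g$u^2);   Ew3u <- mom(g, g$w^3 * g$u)
    Ew3   <- mom(g, g$w^3)
    u0 <- u0 + Ewu; v0 <- v0 + Ew
    varU  <- varU  + Ew2u2 - Ewu^2
    covUV <- covUV + Ew2u - Ewu * Ew
    varV  <- varV  + Ew2 - Ew^2
    dU2dV <- dU2dV + Ew3u2 - Ew * Ew2u2 - 2 * Ewu * Ew2u + 2 * Ewu^2 * Ew
    dUdV2 <- dUdV2 + Ew3u - 2 * Ew * Ew2u - Ewu * Ew2 + 2 * Ewu * Ew^2
    dV3   <- dV3   + Ew3 - 3 * Ew * Ew2 + 2 * Ew^3
  }
  (u0^2 + varU) / v0 -
    (2 * u0 * covUV + dU2dV) / v0^2 +
    (u0^2 * varV + 2 * u0 * dUdV2 + varU * varV + 2 * covUV^2) / v0^3 -
    u0^2 * dV3 / v0^4
}

# E[U^2/V] exactly, via 1/V = integral_0^Inf exp(-sV) ds and independence
kdb_ratio_laplace <- function(G) {
  integrand <- function(s) {
    vapply(s, function(si) {
      la <- vapply(G, function(g) sum(g$wt * exp(-si * g$w)), 0)
      be <- vapply(G, function(g) sum(g$wt * g$w * g$u * exp(-si * g$w)), 0)
      ga <- vapply(G, function(g) sum(g$wt * g$w^2 * g$u^2 * exp(-si * g$w)), 0)
      P <- exp(sum(log(la)))
      val <- P * (sum(ga / la) + sum(be / la)^2 - sum((be / la)^2))
      if (is.finite(val)) val else 0
    }, 0)
  }
  stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                   subdivisions = 400L)$value
}

## ------------------------------------------------------------------
## CDF of a positive linear combination of chi-squared variables
## ------------------------------------------------------------------

#' Distribution function of a weighted sum of chi-squared variables
#'
#' Evaluates \eqn{P(\sum_j \lambda_j \chi^2_{\nu_j} \le x)} for positive
#' coefficients.  The default path is the Ruben-Farebrother series of
#' central chi-squared distribution functions (absolute accuracy about
#' 1e-8), with Imhof-type numerical inversion of the characteristic
#' function as the second path and as the automatic fallback when the
#' series converges too slowly (widely spread coefficients).  Both paths
#' are tested against each other and against Monte Carlo.  This is the
#' computational core of the
#' Biggerstaff-Jackson and Jackson interval estimators, where the
#' coefficients are the eigenvalues of the weighted centering matrix times
#' the covariance of the effect estimates.
#'
#' @param coeffs Positive coefficients \eqn{\lambda_j}.
#' @param dfs Degrees of freedom \eqn{\nu_j} (defaults to 1 each).
#' @param x Evaluation point (scalar).
#' @param method `"ruben"` (default) or `"imhof"`.
#' @return The probability.
#' @export
#' @examples
#' chisq_mix_cdf(1, 4, 5)      # reduces to pchisq(5, 4)
#' pchisq(5, 4)
chisq_mix_cdf <- function(coeffs, dfs = rep(1, length(coeffs)), x,
                          method = c("ruben", "imhof")) {
  method <- match.arg(method)
  if (any(!is.finite(coeffs)) || any(coeffs <= 0))
    stop("all coefficients must be positive", call. = FALSE)
  if (length(dfs) != length(coeffs) || any(dfs <= 0))
    stop("'dfs' must be positive and match 'coeffs'", call. = FALSE)
  if (x <= 0) return(0)
  p <- if (method == "ruben") {
    r <- ruben_cdf(coeffs, dfs, x)
    if (r$converged) r$p else imhof_cdf(coeffs, dfs, x)
  } else imhof_cdf(coeffs, dfs, x)
  min(max(p, 0), 1)
}

imhof_cdf <- function(lam, nu, x) {
  if (diff(range(lam)) < 1e-12 * max(lam))   # common scale: exact
    return(stats::pchisq(x / mean(lam), sum(nu)))
  f <- function(u) {
    th <- 0.5 * colSums(nu * atan(outer(lam, u))) - 0.5 * x * u
    lr <- 0.25 * colSums(nu * log1p(outer(lam^2, u^2)))
    sin(th) / (u * exp(lr))
  }
  # truncate where the envelope 1/(u rho(u)) makes the tail negligible
  # (decay like u^-(1 + sum(nu)/2)), but never below the integrand's own
  # frequency scale
  s <- sum(nu) / 2
  logc <- sum(nu / 2 * log(lam))
  upper <- exp((log(1 / (pi * s * 1e-10)) - logc) / s)
  upper <- min(max(upper, 30 / min(lam)), 1e6)
  I <- tryCatch(
    stats::integrate(f, 0, upper, rel.tol = 1e-9, abs.tol = 1e-11,
                     subdivisions = 5000L)$value,
    error = function(e) NA_real_)
  if (is.na(I)) {
    r <- ruben_cdf(lam, nu, x, maxit = 50000L)
    return(r$p)
  }
  0.5 - I / pi
}

# Ruben (1962) series with Farebrother-style recursion; beta is the usual
# 0.90625 * min(lambda) working constant.  Returns the partial sum and a
# convergence flag based on the remaining series mass.
ruben_cdf <- function(lam, nu, x, tol = 1e-10, maxit = 10000L) {
  beta <- 0.90625 * min(lam)
  r <- 1 - beta / lam
  ntot <- sum(nu)
  a <- exp(0.5 * sum(nu * log(beta / lam)))
  bk <- numeric(maxit)
  ak <- numeric(maxit + 1L)
  ak[1L] <- a
  p <- a * stats::pchisq(x / beta, ntot)
  remainder <- 1 - a
  converged <- FALSE
  for (k in seq_len(maxit)) {
    bk[k] <- sum(nu * r^k)
    ak[k + 1L] <- sum(bk[1:k] * ak[k:1]) / (2 * k)
    p <- p + ak[k + 1L] * stats::pchisq(x / beta, ntot + 2 * k)
    remainder <- remainder - ak[k + 1L]
    if (remainder * stats::pchisq(x / beta, ntot + 2 * k) < tol && k > 3L) {
      converged <- TRUE
      break
    }
  }
  list(p = p, converged = converged)
}

#' @export
print.q_moments <- function(x, ...) {
  cat("Corrected moments of Q\n")
  cat(sprintf("  kappa1 (E[Q])  : %.6f\n", x$kappa1))
  if (is.finite(x$kappa2)) cat(sprintf("  kappa2 (Var[Q]): %.6f\n", x$kappa2))
  cat(sprintf("  family         : %s\n", x$family))
  if (identical(x$family, "SCALED_F"))
    cat(sprintf("  scale c, df2   : %.5f, %.3f\n", x$scale_c, x$df2))
  invisible(x)
}
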