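#' @title Point estimators of the between-study variance
#' @name tau2-point
#' @description
#' Seven moment- and likelihood-based estimators of \eqn{\tau^2}:
#' DerSimonian-Laird (`tau2_dl`), restricted maximum likelihood
#' (`tau2_reml`), Mandel-Paule (`tau2_mp`), Jackson (`tau2_jackson`), and
#' the effect-measure-specific corrected-moment estimators: Welch-type
#' (`tau2_wt`) and corrected DerSimonian-Laird (`tau2_cdl`) for MD, and
#' the corrected first-moment estimator (`tau2_kdb`) for SMD.  All return
#' a `"tau2_result"` object carrying the truncated estimate, the
#' untruncated value where a closed-form negative branch exists, and
#' convergence bookkeeping.  [tau2_estimate()] dispatches on a method name.
NULL

tau2_result <- function(method, estimate, untruncated = estimate,
                        converged = TRUE, iterations = 0L,
                        boundary = FALSE) {
  structure(list(method = method, estimate = max(estimate, 0),
                 untruncated = untruncated, converged = converged,
                 iterations = iterations, boundary = boundary),
            class = "tau2_result")
}

#' @export
print.tau2_result <- function(x, ...) {
  cat(sprintf("tau^2 (%s) = %.4f%s\n", x$method, x$estimate,
              if (x$boundary) " [truncated at 0]" else ""))
  if (!x$converged) cat("  warning: iteration did not converge\n")
  invisible(x)
}

# geometric bracket growth for the monotone-decreasing profile equations;
# returns the root of f (decreasing in tau2) equal to zero, or 0 when
# f(0) < 0 already.
solve_profile <- function(f, records, tol = 1e-10) {
  # the profile equations are monotone nonincreasing in tau2; far to the
  # right the value is negative, so a numerically degenerate evaluation
  # there is treated as such
  fs <- function(t2) {
    val <- f(t2)
    if (!is.finite(val)) -1 else val
  }
  if (fs(0) <= 0) return(list(root = 0, boundary = TRUE))
  hi <- 4 * max(records$variance) * nrow(records)
  while (fs(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e8) stop("failed to bracket the profile equation", call. = FALSE)
  }
  r <- stats::uniroot(fs, c(0, hi), tol = tol)
  list(root = r$root, boundary = FALSE)
}

#' DerSimonian-Laird estimator
#'
#' Closed-form moment estimator
#' \eqn{\hat\tau^2 = \max\{(Q(0) - (K-1))/(W - W^{(2)}/W),\,0\}} with
#' \eqn{w_i = 1/v_i^2}.
#' @param records An [effect_records()] data frame.
#' @return A `"tau2_result"`.
#' @rdname tau2-point
#' @export
tau2_dl <- function(records) {
  check_records(records, caller = "tau2_dl")
  K <- nrow(records)
  w <- 1 / records$variance
  W <- sum(w)
  raw <- (cochran_q(records, 0) - (K - 1)) / (W - sum(w^2) / W)
  tau2_result("DL", raw, untruncated = raw, boundary = raw < 0)
}

#' Restricted maximum likelihood estimator
#'
#' Maximizes the restricted log-likelihood of the marginal model
#' \eqn{\hat\theta_i \sim N(\theta, v_i^2 + \tau^2)} by the standard
#' fixed-point (Fisher-scoring type) iteration, projected to zero at the
#' boundary.  Convergence: relative change below `tol` (default 1e-10),
#' at most `maxit` iterations.
#' @param tol,maxit Convergence tolerance and iteration cap.
#' @rdname tau2-point
#' @export
tau2_reml <- function(records, tol = 1e-10, maxit = 200L) {
  check_records(records, caller = "tau2_reml")
  y <- records$estimate; v <- records$variance
  t2 <- max(tau2_dl(records)$estimate, 0.01 * mean(v))
  conv <- FALSE; it <- 0L
  while (it < maxit) {
    it <- it + 1L
    w <- 1 / (v + t2)
    th <- sum(w * y) / sum(w)
    t2new <- max(0, sum(w^2 * ((y - th)^2 - v)) / sum(w^2) + 1 / sum(w))
    if (abs(t2new - t2) <= tol * (abs(t2) + tol)) { conv <- TRUE; t2 <- t2new; break }
    t2 <- t2new
  }
  if (!conv) warning("REML iteration did not converge; returning last iterate")
  tau2_result("REML", t2, converged = conv, iterations = it,
              boundary = t2 == 0)
}

#' Mandel-Paule estimator
#'
#' Solves \eqn{Q(\tau^2) = K - 1} by monotone root finding; zero with a
#' boundary flag when \eqn{Q(0) < K - 1}.
#' @rdname tau2-point
#' @export
tau2_mp <- function(records) {
  check_records(records, caller = "tau2_mp")
  K <- nrow(records)
  s <- solve_profile(function(t2) cochran_q(records, t2) - (K - 1), records)
  tau2_result("MP", s$root, boundary = s$boundary)
}

# Jackson's generalized-Q weights: reciprocal standard error
jackson_a <- function(records) 1 / sqrt(records$variance)

#' Jackson estimator
#'
#' Moment estimator matching the generalized Q statistic with constant
#' weights \eqn{a_i = 1/v_i} (reciprocal within-study standard error) to
#' its expectation
#' \eqn{E[Q_a] = \sum a_i(v_i^2+\tau^2) - \sum a_i^2(v_i^2+\tau^2)/A},
#' truncated at zero.
#' @rdname tau2-point
#' @export
tau2_jackson <- function(records) {
  check_records(records, caller = "tau2_jackson")
  a <- jackson_a(records)
  A <- sum(a)
  v <- records$variance
  raw <- (gen_q(records, a) - (sum(a * v) - sum(a^2 * v) / A)) /
    (A - sum(a^2) / A)
  tau2_result("J", raw, untruncated = raw, boundary = raw < 0)
}

#' Welch-type estimator (MD only)
#'
#' Mandel-Paule-type estimator that replaces the classical target
#' \eqn{K - 1} by the corrected first moment \eqn{\hat E_{WT}(Q)} of
#' [welch_null_moments()], with the weights, \eqn{p_i} terms and moments
#' re-evaluated at each candidate \eqn{\tau^2}.  The outer iteration stops
#' when successive solutions differ by less than `tol`.
#' @rdname tau2-point
#' @export
tau2_wt <- function(records, tol = 1e-10, maxit = 100L) {
  check_records(records, measure = "MD", need_arm_sd = TRUE,
                caller = "tau2_wt")
  target <- function(t2) welch_null_moments(welch_gamma_terms(records, t2))$kappa1
  s <- solve_profile(function(t2) cochran_q(records, t2) - target(t2),
                     records, tol = tol)
  tau2_result("WT", s$root, boundary = s$boundary)
}

#' Corrected DerSimonian-Laird estimator (MD only)
#'
#' DL-type closed form using the corrected nonnull first moment of Q:
#' \eqn{\hat\tau^2 = \max\{(Q(0) - (K-1) -
#'   2\sum_i \hat w_i^2\hat\gamma_i \hat p_i^2)/(W - W^{(2)}/W),\,0\}}
#' with everything evaluated at \eqn{\tau^2 = 0} weights.  Reduces to
#' [tau2_dl()] exactly when all \eqn{\gamma_i = 0}.
#' @rdname tau2-point
#' @export
tau2_cdl <- function(records) {
  check_records(records, measure = "MD", need_arm_sd = TRUE,
                caller = "tau2_cdl")
  K <- nrow(records)
  gt <- welch_gamma_terms(records, 0)
  S <- sum(gt$w^2 * gt$gamma * gt$p^2)
  w <- gt$w; W <- gt$W
  raw <- (cochran_q(records, 0) - (K - 1) - 2 * S) / (W - sum(w^2) / W)
  tau2_result("CDL", raw, untruncated = raw, boundary = raw < 0)
}

#' Corrected first-moment estimator (SMD only)
#'
#' Solves \eqn{Q(\tau^2) = \hat E(Q; \hat\delta(\tau^2), \tau^2)} where the
#' right-hand side is the corrected expectation of [kdb_expected_q()] and
#' \eqn{\hat\delta(\tau^2)} is the inverse-variance-weighted mean at the
#' current weights.  Truncated at zero.
#' @rdname tau2-point
#' @export
tau2_kdb <- function(records, tol = 1e-8) {
  check_records(records, measure = "SMD", caller = "tau2_kdb")
  ivm <- function(t2) {
    w <- 1 / (records$variance + t2)
    sum(w * records$estimate) / sum(w)
  }
  f <- function(t2)
    cochran_q(records, t2) - kdb_expected_q(records, ivm(t2), t2)$kappa1
  s <- solve_profile(f, records, tol = tol)
  tau2_result("KDB", s$root, boundary = s$boundary)
}

#' Dispatch a tau-squared point estimator by name
#'
#' @param records An [effect_records()] data frame.
#' @param method One of `"DL"`, `"REML"`, `"MP"`, `"J"`, `"WT"`, `"CDL"`,
#'   `"KDB"`.
#' @return A `"tau2_result"`.
#' @export
tau2_estimate <- function(records, method) {
  method <- toupper(method)
  fun <- switch(method,
                DL = tau2_dl, REML = tau2_reml, MP = tau2_mp,
                J = tau2_jackson, WT = tau2_wt, CDL = tau2_cdl,
                KDB = tau2_kdb,
                stop("unknown tau2 method: ", method, call. = FALSE))
  fun(records)
}
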