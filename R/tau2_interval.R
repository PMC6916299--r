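#' @title Interval estimators of the between-study variance
#' @name tau2-interval
#' @description
#' Confidence intervals for \eqn{\tau^2}: Q-profile (`ci_q_profile`),
#' profile likelihood (`ci_profile_likelihood`), Biggerstaff-Jackson
#' (`ci_bj`), Jackson (`ci_jackson`), and the corrected-moment profiles:
#' Welch-type (`ci_wt`, MD) and corrected first-moment (`ci_kdb`, SMD).
#' All return an `"interval_result"`.  With only two studies intervals can
#' be extremely wide; a warning is issued.
NULL

interval_result <- function(method, lower, upper, level,
                            boundary_note = "none") {
  structure(list(lower = max(lower, 0), upper = upper, level = level,
                 method = method, boundary_note = boundary_note),
            class = "interval_result")
}

#' @export
print.interval_result <- function(x, ...) {
  cat(sprintf("%.0f%% CI for tau^2 (%s): (%.4f, %.4f)%s\n",
              100 * x$level, x$method, x$lower, x$upper,
              if (x$boundary_note != "none") paste0(" [", x$boundary_note, "]")
              else ""))
  invisible(x)
}

warn_k2 <- function(records) {
  if (nrow(records) == 2L)
    warning("only two studies: interval estimates of tau^2 may be ",
            "extremely wide or unbounded", call. = FALSE)
}

# Solve Q(tau2) = target for one endpoint; target may be tau2-dependent.
profile_endpoint <- function(records, target_fun, tol = 1e-10) {
  f <- function(t2) cochran_q(records, t2) - target_fun(t2)
  solve_profile(f, records, tol = tol)
}

#' Q-profile interval
#'
#' Inverts the monotone map \eqn{\tau^2 \mapsto Q(\tau^2)} against
#' chi-squared quantiles:
#' \eqn{Q(\tau^2_L) = \chi^2_{K-1;1-\alpha/2}},
#' \eqn{Q(\tau^2_U) = \chi^2_{K-1;\alpha/2}}; endpoints truncate at zero
#' when Q(0) falls below the respective quantile.
#'
#' @param records An [effect_records()] data frame.
#' @param level Confidence level, default 0.95.
#' @return An `"interval_result"`.
#' @rdname tau2-interval
#' @export
ci_q_profile <- function(records, level = 0.95) {
  check_records(records, caller = "ci_q_profile"); warn_k2(records)
  K <- nrow(records); al <- 1 - level
  lo <- profile_endpoint(records, function(t2) stats::qchisq(1 - al / 2, K - 1))
  hi <- profile_endpoint(records, function(t2) stats::qchisq(al / 2, K - 1))
  note <- if (lo$boundary && hi$boundary) "degenerate_zero"
          else if (lo$boundary) "truncated_at_zero" else "none"
  interval_result("QP", lo$root, hi$root, level, note)
}

# profile log-likelihoods: theta profiled out at each tau2
loglik_profile <- function(records, restricted) {
  y <- records$estimate; v <- records$variance
  function(t2) {
    w <- 1 / (v + t2)
    th <- sum(w * y) / sum(w)
    ll <- -0.5 * (sum(log(v + t2)) + sum(w * (y - th)^2))
    if (restricted) ll - 0.5 * log(sum(w)) else ll
  }
}

#' Profile-likelihood interval
#'
#' The set \eqn{\{\tau^2 : 2[\ell_p(\hat\tau^2) - \ell_p(\tau^2)] \le
#' \chi^2_{1;1-\alpha}\}} where \eqn{\ell_p} profiles out the overall
#' effect at each \eqn{\tau^2}.  By default the restricted likelihood is
#' profiled around the REML estimate (`type = "reml"`), which is the
#' variant whose numbers this package's worked example reproduces;
#' `type = "ml"` profiles the ordinary likelihood around the ML estimate.
#'
#' @param type Likelihood used for the profile.
#' @rdname tau2-interval
#' @export
ci_profile_likelihood <- function(records, level = 0.95,
                                  type = c("reml", "ml")) {
  check_records(records, caller = "ci_profile_likelihood"); warn_k2(records)
  type <- match.arg(type)
  lp <- loglik_profile(records, restricted = type == "reml")
  hi0 <- 4 * max(records$variance) * nrow(records)
  opt <- stats::optimize(lp, c(0, hi0), maximum = TRUE, tol = 1e-12)
  t2hat <- opt$maximum; lmax <- opt$objective
  if (lp(0) >= lmax) { t2hat <- 0; lmax <- lp(0) }
  crit <- stats::qchisq(level, 1)
  dev <- function(t2) 2 * (lmax - lp(t2)) - crit
  lower <- if (dev(0) <= 0) 0 else
    stats::uniroot(dev, c(0, t2hat), tol = 1e-10)$root
  hi <- max(t2hat, 1e-4) * 2
  while (dev(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e8) {
      warning("flat likelihood: upper limit taken at widest bracket")
      break
    }
  }
  upper <- if (dev(hi) < 0) hi else
    stats::uniroot(dev, c(t2hat, hi), tol = 1e-10)$root
  note <- if (lower == 0) "truncated_at_zero" else "none"
  interval_result("PL", lower, upper, level, note)
}

# eigenvalues of Sigma^{1/2} A Sigma^{1/2} for the generalized Q with
# constant weights a; Sigma = diag(v + tau2)
q_mix_coeffs <- function(records, a, tau2) {
  s <- sqrt(records$variance + tau2)
  A <- diag(a) - outer(a, a) / sum(a)
  M <- (s %o% s) * A
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > max(ev) * 1e-12]
}

# generic exact-distribution inversion for generalized Q with weights a
ci_mix_inversion <- function(records, a, level, method_label) {
  Qobs <- gen_q(records, a)
  cdf <- function(t2) {
    lam <- q_mix_coeffs(records, a, t2)
    chisq_mix_cdf(lam, rep(1, length(lam)), Qobs)
  }
  al <- 1 - level
  # cdf(t2) at fixed Qobs decreases in t2: larger tau2 shifts Q's
  # distribution up, pushing Qobs into its lower tail
  lo <- if (cdf(0) <= 1 - al / 2) list(root = 0, boundary = TRUE) else
    solve_profile(function(t2) cdf(t2) - (1 - al / 2), records, tol = 1e-9)
  hi <- solve_profile(function(t2) cdf(t2) - al / 2, records, tol = 1e-9)
  if (hi$boundary)
    return(interval_result(method_label, 0, 0, level, "degenerate_zero"))
  note <- if (lo$boundary) "truncated_at_zero" else "none"
  interval_result(method_label, lo$root, hi$root, level, note)
}

#' Biggerstaff-Jackson interval
#'
#' Uses the exact distribution of the classical Q statistic (inverse-
#' variance weights, \eqn{\tau^2 = 0}) under the random-effects model: a
#' positive linear combination of chi-squared variables whose coefficients
#' are the nonzero eigenvalues of the weighted centering matrix times
#' \eqn{\mathrm{diag}(v_i^2 + \tau^2)}, evaluated via [chisq_mix_cdf()].
#' @rdname tau2-interval
#' @export
ci_bj <- function(records, level = 0.95) {
  check_records(records, caller = "ci_bj"); warn_k2(records)
  ci_mix_inversion(records, 1 / records$variance, level, "BJ")
}

#' Jackson interval
#'
#' Same inversion machinery as [ci_bj()] applied to Jackson's generalized
#' Q with constant weights \eqn{a_i = 1/v_i}.
#' @rdname tau2-interval
#' @export
ci_jackson <- function(records, level = 0.95) {
  check_records(records, caller = "ci_jackson"); warn_k2(records)
  ci_mix_inversion(records, jackson_a(records), level, "J")
}

#' Welch-type interval (MD only)
#'
#' Q-profile inversion with the scaled-F quantiles of the corrected null
#' approximation replacing chi-squared quantiles; the moments (hence
#' \eqn{\hat c} and \eqn{\hat f_2}) are re-evaluated at each candidate
#' \eqn{\tau^2} because the weights depend on it.
#' @rdname tau2-interval
#' @export
ci_wt <- function(records, level = 0.95) {
  check_records(records, measure = "MD", need_arm_sd = TRUE,
                caller = "ci_wt"); warn_k2(records)
  K <- nrow(records); al <- 1 - level
  qtarget <- function(p) function(t2) {
    wt_null_quantile(p, welch_null_moments(welch_gamma_terms(records, t2)), K)
  }
  lo <- profile_endpoint(records, qtarget(1 - al / 2))
  hi <- profile_endpoint(records, qtarget(al / 2))
  note <- if (lo$boundary && hi$boundary) "degenerate_zero"
          else if (lo$boundary) "truncated_at_zero" else "none"
  interval_result("WT", lo$root, hi$root, level, note)
}

#' Corrected first-moment interval (SMD only)
#'
#' Q-profile inversion using chi-squared quantiles with fractional degrees
#' of freedom equal to the corrected expectation of Q
#' ([kdb_expected_q()]), re-evaluated (with the inverse-variance mean as
#' the plug-in effect) at each candidate \eqn{\tau^2}.
#' @rdname tau2-interval
#' @export
ci_kdb <- function(records, level = 0.95) {
  check_records(records, measure = "SMD", caller = "ci_kdb"); warn_k2(records)
  al <- 1 - level
  ivm <- function(t2) {
    w <- 1 / (records$variance + t2)
    sum(w * records$estimate) / sum(w)
  }
  qtarget <- function(p) function(t2)
    stats::qchisq(p, df = kdb_expected_q(records, ivm(t2), t2)$kappa1)
  lo <- profile_endpoint(records, qtarget(1 - al / 2), tol = 1e-7)
  hi <- profile_endpoint(records, qtarget(al / 2), tol = 1e-7)
  note <- if (lo$boundary && hi$boundary) "degenerate_zero"
          else if (lo$boundary) "truncated_at_zero" else "none"
  interval_result("KDB", lo$root, hi$root, level, note)
}

#' Dispatch a tau-squared interval estimator by name
#'
#' @param records An [effect_records()] data frame.
#' @param method One of `"QP"`, `"PL"`, `"BJ"`, `"J"`, `"WT"`, `"KDB"`.
#' @param level Confidence level.
#' @return An `"interval_result"`.
#' @export
tau2_interval <- function(records, method, level = 0.95) {
  method <- toupper(method)
  fun <- switch(method,
                QP = ci_q_profile, PL = ci_profile_likelihood,
                BJ = ci_bj, J = ci_jackson, WT = ci_wt, KDB = ci_kdb,
                stop("unknown tau2 interval method: ", method, call. = FALSE))
  fun(records, level = level)
}
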