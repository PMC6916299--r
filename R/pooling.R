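#' @title Point and interval estimation of the overall effect
#' @name pooling
#' @description
#' Overall-effect estimators for a set of effect records at a given value
#' of the between-study variance: inverse-variance weighting with normal
#' critical values ([pool_iv()]; `tau2 = 0` gives the fixed-effect
#' estimator), the Hartung-Knapp-Sidik-Jonkman weighted-residual t
#' interval ([pool_hksj()]), and sample-size (effective-size) weighting
#' with a t interval ([pool_ssw()]).  All intervals are symmetric about
#' their midpoint.
NULL

pooled_result <- function(estimate, se, lower, upper, weighting,
                          tau2_method, ci_family, df, level) {
  structure(list(estimate = estimate, se = se, lower = lower, upper = upper,
                 weighting = weighting, tau2_method = tau2_method,
                 ci_family = ci_family, df = df, level = level,
                 width = upper - lower),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("%s%s estimate %.4f, %.0f%% CI (%.4f, %.4f) [%s]\n",
              x$weighting,
              if (!is.null(x$tau2_method) && nzchar(x$tau2_method))
                paste0("(", x$tau2_method, ")") else "",
              x$estimate, 100 * x$level, x$lower, x$upper, x$ci_family))
  invisible(x)
}

#' Inverse-variance pooled estimate
#'
#' Weighted mean with weights \eqn{w_i = (v_i^2 + \tau^2)^{-1}}, variance
#' \eqn{(\sum w_i)^{-1}} and normal critical values.
#'
#' @param records An [effect_records()] data frame.
#' @param tau2 Between-study variance used in the weights (0 for the
#'   fixed-effect model; typically a [tau2_estimate()] value).
#' @param level Confidence level.
#' @param tau2_method Optional label recording which estimator produced
#'   `tau2`.
#' @return A `"pooled_result"`.
#' @rdname pooling
#' @export
pool_iv <- function(records, tau2 = 0, level = 0.95, tau2_method = "") {
  check_records(records, caller = "pool_iv")
  w <- 1 / (records$variance + tau2)
  est <- sum(w * records$estimate) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  pooled_result(est, se, est - z * se, est + z * se,
                if (tau2 == 0) "FE" else "IV", tau2_method, "NORMAL",
                NA_real_, level)
}

#' Hartung-Knapp-Sidik-Jonkman interval
#'
#' Midpoint is the inverse-variance mean at the supplied `tau2`; the
#' variance is the weighted residual form
#' \deqn{\widehat{Var} = \frac{\sum w_i(\hat\theta_i - \hat\theta)^2 /
#'   (K-1)}{\sum w_i}}
#' with t critical values on \eqn{K - 1} degrees of freedom.  Supplying
#' the corrected-moment estimates of `tau2` gives the HKSJ WT / HKSJ KDB
#' variants.
#' @rdname pooling
#' @export
pool_hksj <- function(records, tau2, level = 0.95, tau2_method = "") {
  check_records(records, caller = "pool_hksj")
  K <- nrow(records)
  if (K == 2L) warning("HKSJ interval with K = 2 is extremely wide",
                       call. = FALSE)
  w <- 1 / (records$variance + tau2)
  est <- sum(w * records$estimate) / sum(w)
  se <- sqrt(sum(w * (records$estimate - est)^2) / ((K - 1) * sum(w)))
  tc <- stats::qt(1 - (1 - level) / 2, K - 1)
  pooled_result(est, se, est - tc * se, est + tc * se,
                "IV", tau2_method, "HKSJ", K - 1, level)
}

#' Sample-size-weighted (SSW) estimate
#'
#' Weighted mean with effective-sample-size weights
#' \eqn{\tilde n_i = n_{iT} n_{iC}/n_i} (no estimated variances in the
#' weights, hence no weight-estimation bias), variance
#' \eqn{\sum \tilde n_i^2 (v_i^2 + \hat\tau^2) / (\sum \tilde n_i)^2} and
#' t critical values on \eqn{K - 1} degrees of freedom.
#' @rdname pooling
#' @export
pool_ssw <- function(records, tau2, level = 0.95, tau2_method = "") {
  check_records(records, caller = "pool_ssw")
  K <- nrow(records)
  nt <- effective_size(records)
  est <- sum(nt * records$estimate) / sum(nt)
  se <- sqrt(sum(nt^2 * (records$variance + tau2)) / sum(nt)^2)
  tc <- stats::qt(1 - (1 - level) / 2, K - 1)
  pooled_result(est, se, est - tc * se, est + tc * se,
                "SSW", tau2_method, "SSW_T", K - 1, level)
}

#' Higgins-Thompson I-squared
#'
#' \eqn{I^2 = 100\,\tau^2/(\tau^2 + s^2)} with the typical within-study
#' variance \eqn{s^2 = (K-1)\sum W_i / ((\sum W_i)^2 - \sum W_i^2)},
#' \eqn{W_i = 1/v_i^2}.  Reported as a percentage.  Note that this
#' diagnostic depends on the precisions of the included studies, not only
#' on the heterogeneity, which limits its interpretability; the
#' heterogeneity variance itself is the better summary.
#'
#' @return Percentage in [0, 100].
#' @rdname pooling
#' @export
i_squared <- function(records, tau2) {
  check_records(records, caller = "i_squared")
  K <- nrow(records)
  W <- 1 / records$variance
  s2 <- (K - 1) * sum(W) / (sum(W)^2 - sum(W^2))
  100 * tau2 / (tau2 + s2)
}
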