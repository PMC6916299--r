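#' Random-effects meta-analysis with corrected-moment heterogeneity
#' estimation
#'
#' Fits the standard random-effects model
#' \eqn{\hat\theta_i \sim N(\theta,\ v_i^2 + \tau^2)} to study-level
#' effect records, estimating the between-study variance by every
#' requested method, attaching the matching confidence intervals, and
#' pooling the overall effect by inverse-variance, HKSJ and sample-size
#' weighting.  This is the package's central fitting function; the
#' returned object has `print`, `summary`, `coef`, `confint`, `predict`,
#' `residuals`, `plot` and `simulate` methods.
#'
#' Method defaults depend on the effect measure: the MD-specific
#' corrected-moment methods (WT, CDL) require per-arm standard deviations
#' and are added for MD records; the SMD-specific corrected first-moment
#' method (KDB) is added for SMD records.
#'
#' @param records An [effect_records()] data frame (see also
#'   [read_dataset()], [md_effect()], [smd_effect()]).
#' @param tau2 Character vector of point-estimator names for
#'   [tau2_estimate()].  `NULL` picks the measure-appropriate default set.
#' @param ci Character vector of interval-estimator names for
#'   [tau2_interval()]; `NULL` as above.
#' @param pool Pooled-effect families to report: subset of
#'   `c("FE", "IV", "HKSJ", "SSW")`.
#' @param level Confidence level for every interval.
#' @return An object of class `"remeta"`: list with the records, the
#'   per-method `tau2` results, `tau2_ci` results, `pooled` results, the
#'   assembled tidy `table`, and the call.
#' @export
#' @examples
#' path <- system.file("extdata", "ocd_smd.csv", package = "remeta")
#' ocd <- read_dataset(path, "effect_level", "SMD")
#' fit <- remeta(ocd, tau2 = c("DL", "MP"), ci = "QP", pool = c("FE", "IV"))
#' fit
remeta <- function(records, tau2 = NULL, ci = NULL,
                   pool = c("FE", "IV", "HKSJ", "SSW"), level = 0.95) {
  check_records(records, caller = "remeta")
  measure <- measure_of(records)
  has_sd <- !anyNA(c(records$sd_treat, records$sd_control))
  if (is.null(tau2))
    tau2 <- if (measure == "MD")
      c("DL", "REML", "MP", "J", if (has_sd) c("WT", "CDL"))
    else c("DL", "REML", "MP", "J", "KDB")
  if (is.null(ci))
    ci <- if (measure == "MD")
      c("QP", "PL", "BJ", "J", if (has_sd) "WT")
    else c("QP", "PL", "BJ", "J", "KDB")
  tau2 <- toupper(tau2); ci <- toupper(ci)
  pool <- match.arg(pool, several.ok = TRUE)
  bad <- intersect(if (measure == "MD") "KDB" else c("WT", "CDL"), tau2)
  if (length(bad))
    stop(sprintf("method %s is not defined for measure %s",
                 paste(bad, collapse = "/"), measure), call. = FALSE)

  t2 <- lapply(tau2, function(m) tau2_estimate(records, m))
  names(t2) <- tau2
  t2ci <- lapply(ci, function(m)
    suppressWarnings(tau2_interval(records, m, level = level)))
  names(t2ci) <- ci

  pooled <- list()
  if ("FE" %in% pool)
    pooled[["FE"]] <- pool_iv(records, 0, level)
  if ("IV" %in% pool)
    for (m in tau2)
      pooled[[paste0("IV:", m)]] <-
        pool_iv(records, t2[[m]]$estimate, level, tau2_method = m)
  if ("HKSJ" %in% pool) {
    hm <- intersect(c("DL", "WT", "KDB"), tau2)
    for (m in hm)
      pooled[[paste0("HKSJ:", m)]] <-
        suppressWarnings(pool_hksj(records, t2[[m]]$estimate, level,
                                   tau2_method = m))
  }
  if ("SSW" %in% pool) {
    sm <- intersect(c("CDL", "WT", "KDB", "MP", "DL"), tau2)[1]
    if (!is.na(sm))
      pooled[[paste0("SSW:", sm)]] <-
        pool_ssw(records, t2[[sm]]$estimate, level, tau2_method = sm)
  }

  fit <- structure(
    list(records = records, measure = measure, level = level,
         tau2 = t2, tau2_ci = t2ci, pooled = pooled,
         q0 = cochran_q(records, 0), call = match.call()),
    class = "remeta")
  fit$table <- build_table(fit)
  fit
}

build_table <- function(fit) {
  rows <- list()
  add <- function(method, tau2 = NA, tau2_l = NA, tau2_u = NA,
                  est = NA, l = NA, u = NA)
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, tau2 = tau2, tau2_lower = tau2_l, tau2_upper = tau2_u,
      estimate = est, lower = l, upper = u,
      width = if (is.na(l)) NA_real_ else u - l)
  if (!is.null(fit$pooled[["FE"]])) {
    p <- fit$pooled[["FE"]]
    add("FE", est = p$estimate, l = p$lower, u = p$upper)
  }
  ci_for <- function(m) {
    # pair each point estimator with its matched interval where one exists
    key <- switch(m, DL = "QP", MP = "QP", REML = "PL", J = "J",
                  WT = "WT", KDB = "KDB", CDL = "QP", NULL)
    if (!is.null(key) && key %in% names(fit$tau2_ci)) fit$tau2_ci[[key]]
    else NULL
  }
  for (m in names(fit$tau2)) {
    iv <- fit$pooled[[paste0("IV:", m)]]
    civ <- ci_for(m)
    add(paste0(m, "&IV"), tau2 = fit$tau2[[m]]$estimate,
        tau2_l = if (is.null(civ)) NA else civ$lower,
        tau2_u = if (is.null(civ)) NA else civ$upper,
        est = if (is.null(iv)) NA else iv$estimate,
        l = if (is.null(iv)) NA else iv$lower,
        u = if (is.null(iv)) NA else iv$upper)
  }
  if ("BJ" %in% names(fit$tau2_ci))
    add("BJ", tau2_l = fit$tau2_ci$BJ$lower, tau2_u = fit$tau2_ci$BJ$upper)
  for (nm in names(fit$pooled)) {
    if (!startsWith(nm, "HKSJ:") && !startsWith(nm, "SSW:")) next
    p <- fit$pooled[[nm]]
    add(sub(":", " ", nm), est = p$estimate, l = p$lower, u = p$upper)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.remeta <- function(x, digits = 4, ...) {
  K <- nrow(x$records)
  cat(sprintf("Random-effects meta-analysis of %d %s studies\n",
              K, x$measure))
  cat(sprintf("Q(0) = %.4f on K-1 = %d df;  I^2 at DL tau2: %.1f%%\n",
              x$q0, K - 1L,
              if ("DL" %in% names(x$tau2))
                i_squared(x$records, x$tau2$DL$estimate) else NA))
  cat("\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(z) ifelse(is.na(z), NA, round(z, digits)))
  print(tab, row.names = FALSE, na.print = "")
  trunc <- names(Filter(function(t) t$boundary, x$tau2))
  if (length(trunc))
    cat("\n(tau^2 truncated at zero for:", paste(trunc, collapse = ", "), ")\n")
  invisible(x)
}

#' @export
summary.remeta <- function(object, ...) {
  object
}

#' @export
coef.remeta <- function(object, ...) {
  vapply(object$pooled, function(p) p$estimate, 0)
}

#' Confidence intervals from a fitted meta-analysis
#'
#' @param object A `"remeta"` fit.
#' @param parm `"effect"` for the pooled-effect intervals, `"tau2"` for
#'   the heterogeneity-variance intervals, or `"all"`.
#' @param level Ignored (fixed at fitting time).
#' @param ... Unused.
#' @export
confint.remeta <- function(object, parm = c("all", "effect", "tau2"),
                           level = NULL, ...) {
  parm <- match.arg(parm)
  eff <- do.call(rbind, lapply(names(object$pooled), function(nm) {
    p <- object$pooled[[nm]]
    data.frame(parameter = "effect", method = nm,
               lower = p$lower, upper = p$upper)
  }))
  tau <- do.call(rbind, lapply(names(object$tau2_ci), function(nm) {
    ci <- object$tau2_ci[[nm]]
    data.frame(parameter = "tau2", method = nm,
               lower = ci$lower, upper = ci$upper)
  }))
  out <- switch(parm, all = rbind(eff, tau), effect = eff, tau2 = tau)
  rownames(out) <- NULL
  out
}

#' Predicted overall effect
#'
#' Returns the pooled estimate, standard error and confidence interval of
#' the requested pooling combination.
#'
#' @param object A `"remeta"` fit.
#' @param pooling Name of one element of `object$pooled` (default: first).
#' @param ... Unused.
#' @export
predict.remeta <- function(object, pooling = NULL, ...) {
  if (is.null(pooling)) pooling <- names(object$pooled)[1]
  p <- object$pooled[[pooling]]
  if (is.null(p)) stop("no pooled result named '", pooling, "'", call. = FALSE)
  data.frame(pooling = pooling, estimate = p$estimate, se = p$se,
             lower = p$lower, upper = p$upper)
}

#' @export
residuals.remeta <- function(object, tau2_method = NULL, ...) {
  t2 <- if (is.null(tau2_method)) object$tau2[[1]]$estimate
        else object$tau2[[toupper(tau2_method)]]$estimate
  w <- 1 / (object$records$variance + t2)
  th <- sum(w * object$records$estimate) / sum(w)
  (object$records$estimate - th) * sqrt(w)
}

#' Q-profile plot of a fitted meta-analysis
#'
#' Plots \eqn{Q(\tau^2)} over a range covering the widest fitted interval,
#' with the chi-squared reference quantiles and the fitted point estimates
#' marked.  This is the geometry underlying all profile-type interval
#' estimators.
#'
#' @param x A `"remeta"` fit.
#' @param ... Passed to [plot()].
#' @export
plot.remeta <- function(x, ...) {
  K <- nrow(x$records)
  upper <- max(c(vapply(x$tau2_ci, function(ci)
    if (is.finite(ci$upper)) ci$upper else NA_real_, 0),
    vapply(x$tau2, function(t) t$estimate, 0)), na.rm = TRUE)
  ts <- seq(0, max(upper * 1.2, 1e-3), length.out = 200)
  qs <- vapply(ts, function(t) cochran_q(x$records, t), 0)
  al <- 1 - x$level
  plot(ts, qs, type = "l", xlab = expression(tau^2),
       ylab = expression(Q(tau^2)), ...)
  graphics::abline(h = stats::qchisq(c(al / 2, 1 - al / 2), K - 1),
                   lty = 3, col = "grey40")
  graphics::abline(h = K - 1, lty = 2, col = "grey60")
  for (t in x$tau2)
    graphics::points(t$estimate, cochran_q(x$records, t$estimate), pch = 19)
  invisible(x)
}

#' Simulate replicate datasets from a fitted meta-analysis
#'
#' Draws new meta-analyses from the fitted random-effects model, using the
#' study sizes of the original data, the first fitted tau-squared value
#' and the first pooled estimate (or supplied overrides), via
#' [simulate_md()] / [simulate_smd()].
#'
#' @param object A `"remeta"` fit.
#' @param nsim Number of replicate datasets.
#' @param seed Seed for the simulation substreams.
#' @param tau2,effect Optional parameter overrides.
#' @param ... Unused.
#' @return A list of `nsim` [effect_records()] data frames.
#' @export
simulate.remeta <- function(object, nsim = 1, seed = 1,
                            tau2 = NULL, effect = NULL, ...) {
  rec <- object$records
  if (is.null(tau2)) tau2 <- object$tau2[[1]]$estimate
  if (is.null(effect)) effect <- object$pooled[[1]]$estimate
  n <- rec$n_treat + rec$n_control
  cfg <- sim_config(object$measure, K = nrow(rec), n = n,
                    q = sum(rec$n_control) / sum(n), effect = effect,
                    tau2 = tau2,
                    sigma2_treat = if (anyNA(rec$sd_treat)) 1
                                   else mean(rec$sd_treat^2),
                    sigma2_control = if (anyNA(rec$sd_control)) 1
                                     else mean(rec$sd_control^2),
                    reps = nsim, seed = seed)
  # arm sizes must match the data exactly, not the q-derived split
  cfg$n_treat <- rec$n_treat; cfg$n_control <- rec$n_control
  gen <- if (object$measure == "MD") simulate_md else simulate_smd
  lapply(seq_len(nsim), function(r) gen(cfg, r))
}
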