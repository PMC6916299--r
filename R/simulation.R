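#' Configuration of a simulated meta-analysis design
#'
#' Collects the parameters of one cell of the factorial simulation design:
#' effect measure, number of studies, total per-study sample sizes (a
#' scalar for equal sizes, or a vector pattern that is recycled across
#' studies as in the unequal-size designs), control-arm fraction `q`,
#' true overall effect, between-study variance, and (for MD) the true
#' within-study variances of the two arms.  Arm sizes are derived as
#' \eqn{n_{iT} = \lceil (1-q) n_i \rceil}, \eqn{n_{iC} = n_i - n_{iT}}.
#'
#' @param measure `"MD"` or `"SMD"`.
#' @param K Number of studies.
#' @param n Total study sizes: scalar, or a pattern recycled to length `K`
#'   (e.g. `c(12, 16, 18, 20, 84)` used twice for `K = 10`).
#' @param q Control-arm fraction in (0, 1).
#' @param effect True overall effect (mu for MD, delta for SMD).
#' @param tau2 True between-study variance.
#' @param sigma2_treat,sigma2_control True arm variances (MD only).
#' @param reps Number of replications a grid run performs.
#' @param seed Master seed; each replicate derives its own substream so
#'   any single replicate is reproducible in isolation.
#' @return A `"sim_config"` list.
#' @export
#' @examples
#' cfg <- sim_config("MD", K = 5, n = 20, q = 0.75, effect = 0,
#'                   tau2 = 0.5, sigma2_treat = 2, sigma2_control = 1)
#' head(simulate_md(cfg, rep_index = 1))
sim_config <- function(measure = c("MD", "SMD"), K, n, q = 0.5,
                       effect = 0, tau2 = 0,
                       sigma2_treat = 1, sigma2_control = 1,
                       reps = 2000L, seed = 1L) {
  measure <- match.arg(measure)
  stopifnot(K >= 2, all(n >= 4), q > 0, q < 1, tau2 >= 0, reps >= 1)
  sizes <- rep_len(n, K)
  n_treat <- as.integer(ceiling((1 - q) * sizes))
  n_control <- as.integer(sizes - n_treat)
  if (any(n_control < 2) || any(n_treat < 2))
    stop("derived arm sizes below 2; increase n", call. = FALSE)
  structure(list(measure = measure, K = as.integer(K), sizes = sizes,
                 n_treat = n_treat, n_control = n_control, q = q,
                 effect = effect, tau2 = tau2,
                 sigma2_treat = sigma2_treat,
                 sigma2_control = sigma2_control,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "sim_config")
}

#' Unequal study-size patterns of the factorial designs
#'
#' The skewed five-study size patterns (skewness 1.464) used in the
#' unequal-size simulation cells, indexed by their average size.
#'
#' @param nbar Average study size: 30, 60, 100 or 160.
#' @return Integer vector of five total study sizes.
#' @export
unequal_sizes <- function(nbar) {
  switch(as.character(nbar),
         "30" = c(12L, 16L, 18L, 20L, 84L),
         "60" = c(24L, 32L, 36L, 40L, 168L),
         "100" = c(64L, 72L, 76L, 80L, 208L),
         "160" = c(124L, 132L, 136L, 140L, 268L),
         stop("no stored pattern for nbar = ", nbar, call. = FALSE))
}

# deterministic per-replicate substream (keeps seeds below 2^31)
rep_seed <- function(seed, rep_index) {
  (as.double(seed) * 48271 + as.double(rep_index) * 16807) %% 2147483629
}

#' Simulate one mean-difference meta-analysis
#'
#' Generative model: per-arm sample variances
#' \eqn{s_{ij}^2 \sim \sigma_{ij}^2 \chi^2_{n_{ij}-1}/(n_{ij}-1)}, and
#' effect estimates
#' \eqn{y_i \sim N(\mu,\ \sigma_{iT}^2/n_{iT} + \sigma_{iC}^2/n_{iC} +
#' \tau^2)}; the estimated within-study variance is
#' \eqn{v_i^2 = s_{iT}^2/n_{iT} + s_{iC}^2/n_{iC}}.  Records carry the
#' simulated arm standard deviations so the corrected-moment estimators
#' can be applied.
#'
#' @param config A `"sim_config"` with `measure = "MD"`.
#' @param rep_index Replicate number; together with the config seed it
#'   determines the substream, so any replicate can be regenerated alone.
#' @return An [effect_records()] data frame.
#' @export
simulate_md <- function(config, rep_index = 1L) {
  stopifnot(inherits(config, "sim_config"), config$measure == "MD")
  set.seed(rep_seed(config$seed, rep_index))
  nT <- config$n_treat; nC <- config$n_control; K <- config$K
  s2T <- config$sigma2_treat * stats::rchisq(K, nT - 1) / (nT - 1)
  s2C <- config$sigma2_control * stats::rchisq(K, nC - 1) / (nC - 1)
  y <- stats::rnorm(K, config$effect,
                    sqrt(config$sigma2_treat / nT +
                         config$sigma2_control / nC + config$tau2))
  effect_records(estimate = y, variance = s2T / nT + s2C / nC,
                 n_treat = nT, n_control = nC, measure = "MD",
                 sd_treat = sqrt(s2T), sd_control = sqrt(s2C))
}

#' Simulate one standardized-mean-difference meta-analysis
#'
#' Generative model: true effects \eqn{\delta_i \sim N(\delta, \tau^2)};
#' Hedges's \eqn{g_i} drawn directly from its scaled noncentral t
#' distribution,
#' \eqn{g_i = J(m_i)\,T_i/\sqrt{\tilde n_i}} with
#' \eqn{T_i \sim t_{m_i}(\sqrt{\tilde n_i}\,\delta_i)}; within-study
#' variances from the unbiased variance formula of [smd_effect()].
#'
#' @param config A `"sim_config"` with `measure = "SMD"`.
#' @inheritParams simulate_md
#' @return An [effect_records()] data frame.
#' @export
simulate_smd <- function(config, rep_index = 1L) {
  stopifnot(inherits(config, "sim_config"), config$measure == "SMD")
  set.seed(rep_seed(config$seed, rep_index))
  nT <- config$n_treat; nC <- config$n_control; K <- config$K
  m <- nT + nC - 2L
  ntil <- nT * nC / (nT + nC)
  J <- hedges_j(m)
  deli <- stats::rnorm(K, config$effect, sqrt(config$tau2))
  Tnc <- (stats::rnorm(K) + sqrt(ntil) * deli) /
    sqrt(stats::rchisq(K, m) / m)
  g <- J * Tnc / sqrt(ntil)
  v <- 1 / ntil + (1 - (m - 2) / (m * J^2)) * g^2
  effect_records(estimate = g, variance = v, n_treat = nT, n_control = nC,
                 measure = "SMD")
}

#' Monte-Carlo standard error of an estimated coverage
#'
#' \eqn{\sqrt{p(1-p)/R}} at the nominal level `p` and `reps` replications;
#' with `p = 0.95` and 10,000 replications this is 0.00218.
#'
#' @param level Nominal coverage.
#' @param reps Number of replications.
#' @export
mc_se_coverage <- function(level = 0.95, reps) sqrt(level * (1 - level) / reps)

#' Run a factorial simulation grid
#'
#' For each configuration, generates `reps` meta-analyses, applies the
#' requested tau-squared point estimators, interval estimators and pooled
#' estimators, and summarizes bias and MSE of \eqn{\hat\tau^2}, bias and
#' MSE of the pooled effect, and empirical coverage and mean width of every
#' interval.  Replicate failures of individual estimators are counted, not
#' fatal.  Seeding is per replicate, so results are invariant to chunking
#' of the replications.
#'
#' @param configs A `"sim_config"` or list of them.
#' @param tau2_methods Character vector of [tau2_estimate()] methods.
#' @param ci_methods Character vector of [tau2_interval()] methods
#'   (`"oracle"` is accepted as a harness check: it always covers).
#' @param pool_methods Character vector from `"FE"`, `"IV"`, `"HKSJ"`,
#'   `"SSW"`; `"IV"`, `"HKSJ"` and `"SSW"` use the first tau2 method's
#'   estimate unless `pool_tau2` names one.
#' @param pool_tau2 Tau2 method feeding the pooled estimators.
#' @param reps Optional override of each config's replication count.
#' @param level Nominal level of all intervals.
#' @param untruncated Summarize the untruncated tau2 estimates where a
#'   closed-form negative branch exists (default uses truncated values, as
#'   reported to a user).
#' @return A data frame with one row per (config, method, metric).
#' @export
run_grid <- function(configs, tau2_methods = "DL", ci_methods = character(),
                     pool_methods = character(), pool_tau2 = NULL,
                     reps = NULL, level = 0.95, untruncated = FALSE) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(length(configs) > 0)
  out <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    R <- if (is.null(reps)) cfg$reps else as.integer(reps)
    gen <- if (cfg$measure == "MD") simulate_md else simulate_smd
    t2hat <- matrix(NA_real_, R, length(tau2_methods),
                    dimnames = list(NULL, tau2_methods))
    cover <- matrix(NA, R, length(ci_methods),
                    dimnames = list(NULL, ci_methods))
    cwidth <- matrix(NA_real_, R, length(ci_methods),
                     dimnames = list(NULL, ci_methods))
    phat <- matrix(NA_real_, R, length(pool_methods),
                   dimnames = list(NULL, pool_methods))
    pcover <- matrix(NA, R, length(pool_methods),
                     dimnames = list(NULL, pool_methods))
    failures <- 0L
    for (r in seq_len(R)) {
      rec <- gen(cfg, r)
      ptau <- NULL
      for (tm in tau2_methods) {
        res <- tryCatch(tau2_estimate(rec, tm), error = function(e) NULL)
        if (is.null(res)) { failures <- failures + 1L; next }
        t2hat[r, tm] <- if (untruncated) res$untruncated else res$estimate
        if (is.null(ptau)) ptau <- res$estimate
      }
      if (!is.null(pool_tau2))
        ptau <- tryCatch(tau2_estimate(rec, pool_tau2)$estimate,
                         error = function(e) NULL)
      for (cm in ci_methods) {
        iv <- if (identical(cm, "oracle"))
          list(lower = 0, upper = Inf)
        else tryCatch(
          suppressWarnings(tau2_interval(rec, cm, level = level)),
          error = function(e) NULL)
        if (is.null(iv)) { failures <- failures + 1L; next }
        cover[r, cm] <- iv$lower <= cfg$tau2 && cfg$tau2 <= iv$upper
        cwidth[r, cm] <- iv$upper - iv$lower
      }
      if (length(pool_methods) && !is.null(ptau)) {
        for (pm in pool_methods) {
          pr <- tryCatch(switch(pm,
                 FE = pool_iv(rec, 0, level),
                 IV = pool_iv(rec, ptau, level),
                 HKSJ = suppressWarnings(pool_hksj(rec, ptau, level)),
                 SSW = pool_ssw(rec, ptau, level),
                 stop("unknown pool method: ", pm)),
               error = function(e) NULL)
          if (is.null(pr)) { failures <- failures + 1L; next }
          phat[r, pm] <- pr$estimate
          pcover[r, pm] <- pr$lower <= cfg$effect && cfg$effect <= pr$upper
        }
      }
    }
    row <- function(method, metric, value)
      data.frame(config = ci, measure = cfg$measure, K = cfg$K,
                 n = mean(cfg$sizes), q = cfg$q, effect = cfg$effect,
                 tau2 = cfg$tau2, reps = R, method = method,
                 metric = metric, value = value)
    for (tm in tau2_methods) {
      est <- t2hat[, tm]
      out[[length(out) + 1L]] <- row(tm, "tau2_bias",
                                     mean(est, na.rm = TRUE) - cfg$tau2)
      out[[length(out) + 1L]] <- row(tm, "tau2_mse",
                                     mean((est - cfg$tau2)^2, na.rm = TRUE))
    }
    for (cm in ci_methods) {
      out[[length(out) + 1L]] <- row(cm, "tau2_coverage",
                                     mean(cover[, cm], na.rm = TRUE))
      out[[length(out) + 1L]] <- row(cm, "tau2_ci_width",
                                     mean(cwidth[, cm], na.rm = TRUE))
    }
    for (pm in pool_methods) {
      out[[length(out) + 1L]] <- row(pm, "effect_bias",
                                     mean(phat[, pm], na.rm = TRUE) - cfg$effect)
      out[[length(out) + 1L]] <- row(pm, "effect_mse",
                                     mean((phat[, pm] - cfg$effect)^2,
                                          na.rm = TRUE))
      out[[length(out) + 1L]] <- row(pm, "effect_coverage",
                                     mean(pcover[, pm], na.rm = TRUE))
    }
    out[[length(out) + 1L]] <- row("harness", "failures", failures)
    out[[length(out) + 1L]] <- row("harness", "mc_se_coverage",
                                   mc_se_coverage(level, R))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
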