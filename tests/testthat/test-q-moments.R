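test_that("Cochran's Q: degenerate, two-study closed form, monotone profile", {
  expect_equal(cochran_q(homog_records(), 0), 0)

  r2 <- effect_records(c(0.8, 0.2), c(0.04, 0.09), c(30, 25), c(30, 25), "SMD")
  w <- 1 / c(0.04, 0.09)
  closed <- (0.8 - 0.2)^2 * prod(w) / sum(w)
  expect_equal(cochran_q(r2, 0), closed, tolerance = 1e-12)

  qs <- vapply(seq(0, 1, by = 0.1), function(t) cochran_q(ocd_records(), t), 0)
  expect_true(all(diff(qs) < 0))

  expect_error(cochran_q(effect_records(1, .1, 10, 10, "SMD")), "at least 2")
})

test_that("Q is location invariant and scales as expected", {
  r <- toy_md()
  q1 <- cochran_q(r, 0.2)
  shifted <- r; shifted$estimate <- r$estimate + 5
  expect_equal(cochran_q(shifted, 0.2), q1, tolerance = 1e-10)
  scaled <- r
  scaled$estimate <- r$estimate * 3
  scaled$variance <- r$variance * 9
  expect_equal(cochran_q(scaled, 0.2 * 9), q1, tolerance = 1e-10)
})

test_that("Welch gamma terms: closed form, positivity, limits, duplicate coding", {
  m <- 10
  r <- md_effect(arm_summary(m, 1, 1), arm_summary(m, 0, 1))
  gt <- welch_gamma_terms(r, 0)
  expect_equal(gt$gamma, 2 / (m^2 * (m - 1)), tolerance = 1e-14)

  r <- toy_md(K = 8, seed = 3)
  gt <- welch_gamma_terms(r, 0.1)
  expect_true(all(gt$gamma > 0))
  expect_equal(sum(1 - gt$p), 1, tolerance = 1e-12)

  # independent direct coding
  gam <- r$sd_treat^4 / (r$n_treat^2 * (r$n_treat - 1)) +
    r$sd_control^4 / (r$n_control^2 * (r$n_control - 1))
  expect_close(gt$gamma, gam, 1e-14)

  big <- md_effect(arm_summary(10^6, 1, 1), arm_summary(10^6, 0, 1))
  expect_lt(welch_gamma_terms(big, 0)$gamma, 1e-15)

  nosd <- effect_records(1, 0.1, 10, 10, "MD")
  expect_error(welch_gamma_terms(nosd), "standard deviations")
})

test_that("corrected null moments exceed the classical ones and vanish in the limit", {
  r <- toy_md(K = 6, seed = 11, n = 12)
  mom <- welch_null_moments(welch_gamma_terms(r, 0))
  K <- 6
  expect_gt(mom$kappa1, K - 1)
  expect_gt(mom$kappa2, 2 * (K - 1))

  big <- do.call(rbind, lapply(1:6, function(i)
    md_effect(arm_summary(10^5, i / 10, 1), arm_summary(10^5, 0, 1), study = i)))
  attr(big, "measure") <- "MD"; class(big) <- c("effect_records", "data.frame")
  momb <- welch_null_moments(welch_gamma_terms(big, 0))
  expect_lt(momb$kappa1 - (K - 1), 1e-3)
  expect_lt(momb$kappa2 - 2 * (K - 1), 1e-2)
})

test_that("corrected first moment of Q for MD matches a null simulation", {
  # transcription guard: kappa1 against the empirical mean of Q
  K <- 3; nT <- 30L; nC <- 20L; s2T <- 2; s2C <- 1
  sig2 <- s2T / nT + s2C / nC
  rec <- effect_records(rep(0, K), rep(sig2, K), rep(nT, K), rep(nC, K),
                        "MD", sd_treat = rep(sqrt(s2T), K),
                        sd_control = rep(sqrt(s2C), K))
  # kappa1 evaluated with the true variances plugged in
  mom <- welch_null_moments(welch_gamma_terms(rec, 0))
  set.seed(8)
  R <- 200000
  y <- matrix(rnorm(K * R, 0, sqrt(sig2)), K)
  v <- s2T * matrix(rchisq(K * R, nT - 1), K) / (nT - 1) / nT +
       s2C * matrix(rchisq(K * R, nC - 1), K) / (nC - 1) / nC
  w <- 1 / v
  mu <- colSums(w * y) / colSums(w)
  Q <- colSums(w * (y - rep(mu, each = K))^2)
  se <- sd(Q) / sqrt(R)
  # allow the O(1/n^2) truncation residue on top of MC noise
  expect_lt(abs(mean(Q) - mom$kappa1), 3 * se + 0.01)
})

test_that("scaled-F moment matching round-trips and falls back sensibly", {
  fit <- match_scaled_f(9.4, 20.3, 10)
  expect_equal(fit$family, "SCALED_F")
  k1 <- 9
  mean_fit <- fit$scale_c * fit$df2 / (fit$df2 - 2)
  var_fit <- 2 * fit$scale_c^2 * fit$df2^2 * (k1 + fit$df2 - 2) /
    (k1 * (fit$df2 - 2)^2 * (fit$df2 - 4))
  expect_lt(abs(mean_fit - 9.4), 1e-8)
  expect_lt(abs(var_fit - 20.3), 1e-8)

  # classical moments: chi-square limit (quantiles within 1% for K = 10)
  cl <- match_scaled_f(9, 18, 10)
  expect_equal(cl$family, "CHISQ_MOMENT")
  mom <- list(kappa1 = 9, kappa2 = 18, scale_c = cl$scale_c,
              df2 = cl$df2, family = cl$family)
  for (p in c(0.025, 0.5, 0.975)) {
    q1 <- remeta:::wt_null_quantile(p, mom, 10)
    expect_lt(abs(q1 / qchisq(p, 9) - 1), 0.01)
  }
})

test_that("the matched scaled F beats the chi-square in the null upper tail", {
  # K = 5 MD studies of size 20: empirical .975 quantile of Q should be
  # closer to the corrected approximation than to chi-square(4)
  K <- 5; nT <- 10L; nC <- 10L
  rec <- effect_records(rep(0, K), rep(0.2, K), rep(nT, K), rep(nC, K),
                        "MD", sd_treat = rep(1, K), sd_control = rep(1, K))
  mom <- welch_null_moments(welch_gamma_terms(rec, 0))
  set.seed(21)
  R <- 100000
  y <- matrix(rnorm(K * R, 0, sqrt(0.2)), K)
  v <- matrix(rchisq(K * R, 9), K) / 9 / 10 + matrix(rchisq(K * R, 9), K) / 9 / 10
  w <- 1 / v
  mu <- colSums(w * y) / colSums(w)
  Q <- colSums(w * (y - rep(mu, each = K))^2)
  emp <- quantile(Q, 0.975)
  qf_corr <- remeta:::wt_null_quantile(0.975, mom, K)
  expect_lt(abs(emp - qf_corr), abs(emp - qchisq(0.975, K - 1)))
})

test_that("corrected expected Q for SMD: asymptotic limit and Monte-Carlo oracle", {
  K <- 5
  mb <- 4998; Jb <- hedges_j(mb); bb <- 1 - (mb - 2) / (mb * Jb^2)
  big <- effect_records(rep(0.5, K), rep(1 / 1250 + bb * 0.25, K),
                        rep(2500L, K), rep(2500L, K), "SMD")
  e <- kdb_expected_q(big, 0.5, 0)
  expect_equal(e$family, "CHISQ_MOMENT")
  expect_lt(abs(e$kappa1 - (K - 1)), 0.02)

  # K = 5, n = 20, delta = 0.5, tau2 = 0: kappa1 vs mean of simulated Q
  nT <- rep(10L, K); nC <- rep(10L, K); m <- 18; ntil <- 5
  J <- hedges_j(m); b3 <- 1 - (m - 2) / (m * J^2)
  rec <- effect_records(rep(0.5, K), rep(1 / ntil + b3 * 0.25, K),
                        nT, nC, "SMD")
  e <- kdb_expected_q(rec, 0.5, 0)
  set.seed(5)
  R <- 200000
  g <- J * matrix((rnorm(K * R) + sqrt(ntil) * 0.5) /
                    sqrt(rchisq(K * R, m) / m), K) / sqrt(ntil)
  v <- 1 / ntil + b3 * g^2
  w <- 1 / v
  mu <- colSums(w * g) / colSums(w)
  Q <- colSums(w * (g - rep(mu, each = K))^2)
  expect_lt(abs(mean(Q) - e$kappa1), 3 * sd(Q) / sqrt(R))

  # the two ratio-term evaluations agree
  e2 <- kdb_expected_q(rec, 0.5, 0, ratio = "laplace")
  expect_lt(abs(e$kappa1 - e2$kappa1), 1e-3)
})

test_that("the corrected expectation tracks Q's mean under heterogeneity too", {
  K <- 8; nT <- rep(12L, K); nC <- rep(12L, K)
  m <- 22; ntil <- 6; J <- hedges_j(m); b3 <- 1 - (m - 2) / (m * J^2)
  tau2 <- 0.4; delta <- 0.8
  rec <- effect_records(rep(delta, K), rep(1 / ntil + b3 * delta^2, K),
                        nT, nC, "SMD")
  e <- kdb_expected_q(rec, delta, tau2)
  set.seed(31)
  R <- 100000
  deli <- matrix(rnorm(K * R, delta, sqrt(tau2)), K)
  g <- J * (matrix(rnorm(K * R), K) + sqrt(ntil) * deli) /
    sqrt(matrix(rchisq(K * R, m), K) / m) / sqrt(ntil)
  v <- 1 / ntil + b3 * g^2
  w <- 1 / (v + tau2)
  mu <- colSums(w * g) / colSums(w)
  Q <- colSums(w * (g - rep(mu, each = K))^2)
  expect_lt(abs(mean(Q) - e$kappa1), 3 * sd(Q) / sqrt(R) + 0.01)
})

test_that("chi-square mixture CDF: reductions, Monte Carlo, and both paths agree", {
  for (x in c(1, 5, 10))
    for (df in c(1, 4)) {
      expect_lt(abs(chisq_mix_cdf(1, df, x) - pchisq(x, df)), 1e-10)
      expect_lt(abs(chisq_mix_cdf(1, df, x, method = "ruben") -
                      pchisq(x, df)), 1e-8)
    }

  # equal coefficients collapse to a scaled chi-square
  lam <- rep(0.7, 4); dfs <- c(1, 2, 1, 3)
  for (x in c(2, 6, 12))
    expect_lt(abs(chisq_mix_cdf(lam, dfs, x) - pchisq(x / 0.7, sum(dfs))),
              1e-9)

  # mixed case vs Monte Carlo
  set.seed(14)
  R <- 1e6
  draws <- 0.5 * rchisq(R, 2) + 1.5 * rchisq(R, 3)
  for (x in c(2, 4, 6, 9, 14)) {
    p_mc <- mean(draws <= x)
    se <- sqrt(p_mc * (1 - p_mc) / R)
    expect_lt(abs(chisq_mix_cdf(c(0.5, 1.5), c(2, 3), x) - p_mc), 3 * se)
  }

  # imhof and ruben agree away from the reductions as well
  lam <- c(0.2, 0.9, 2.4); dfs <- c(1, 1, 2)
  for (x in c(1, 4, 8, 15))
    expect_lt(abs(chisq_mix_cdf(lam, dfs, x, method = "imhof") -
                    chisq_mix_cdf(lam, dfs, x, method = "ruben")), 1e-8)

  # shape
  xs <- seq(0.1, 40, length.out = 30)
  ps <- vapply(xs, function(x) chisq_mix_cdf(c(1, 2), c(2, 2), x), 0)
  expect_true(all(diff(ps) >= 0))
  expect_lt(ps[1], 0.01)
  expect_gt(ps[30], 0.99)

  expect_error(chisq_mix_cdf(c(1, -1), c(1, 1), 2), "positive")
})
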