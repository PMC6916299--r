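test_that("the worked example reproduces the published interval estimates", {
  ocd <- ocd_records()
  qp <- ci_q_profile(ocd)
  expect_lt(abs(qp$lower - 0.0991), 5e-4)
  expect_lt(abs(qp$upper - 1.1002), 5e-4)
  bj <- ci_bj(ocd)
  expect_lt(abs(bj$lower - 0.0494), 5e-4)
  expect_lt(abs(bj$upper - 0.5128), 5e-4)
  j <- ci_jackson(ocd)
  expect_lt(abs(j$lower - 0.1315), 5e-4)
  expect_lt(abs(j$upper - 0.8214), 5e-4)
  pl <- ci_profile_likelihood(ocd)
  expect_equal(pl$lower, 0)
  expect_lt(abs(pl$upper - 0.6028), 5e-4)
  expect_equal(pl$boundary_note, "truncated_at_zero")
})

test_that("Q-profile agrees with an independent implementation", {
  skip_if_not_installed("metafor")
  ocd <- ocd_records()
  fit <- metafor::rma(ocd$estimate, ocd$variance, method = "REML")
  ref <- confint(fit)$random
  qp <- ci_q_profile(ocd)
  expect_lt(abs(qp$lower - ref["tau^2", "ci.lb"]), 1e-4)
  expect_lt(abs(qp$upper - ref["tau^2", "ci.ub"]), 1e-4)
})

test_that("profile-type endpoints satisfy their defining equations", {
  ocd <- ocd_records()
  K <- nrow(ocd)
  qp <- ci_q_profile(ocd)
  expect_lt(abs(cochran_q(ocd, qp$lower) - qchisq(0.975, K - 1)), 1e-8)
  expect_lt(abs(cochran_q(ocd, qp$upper) - qchisq(0.025, K - 1)), 1e-8)

  md <- toy_md(K = 8, seed = 5, tau2 = 0.6)
  wt <- ci_wt(md)
  if (wt$lower > 0) {
    mom_l <- welch_null_moments(welch_gamma_terms(md, wt$lower))
    expect_lt(abs(cochran_q(md, wt$lower) -
                    remeta:::wt_null_quantile(0.975, mom_l, 8)), 1e-8)
  }
  mom_u <- welch_null_moments(welch_gamma_terms(md, wt$upper))
  expect_lt(abs(cochran_q(md, wt$upper) -
                  remeta:::wt_null_quantile(0.025, mom_u, 8)), 1e-8)

  kdb <- ocd_kdb()$ci
  ivm <- function(t2) {
    w <- 1 / (ocd$variance + t2); sum(w * ocd$estimate) / sum(w)
  }
  eL <- kdb_expected_q(ocd, ivm(kdb$lower), kdb$lower)$kappa1
  eU <- kdb_expected_q(ocd, ivm(kdb$upper), kdb$upper)$kappa1
  expect_lt(abs(cochran_q(ocd, kdb$lower) - qchisq(0.975, eL)), 1e-5)
  expect_lt(abs(cochran_q(ocd, kdb$upper) - qchisq(0.025, eU)), 1e-5)
})

test_that("exact-distribution endpoints invert the mixture CDF", {
  ocd <- ocd_records()
  bj <- ci_bj(ocd)
  a <- 1 / ocd$variance
  Qobs <- remeta:::gen_q(ocd, a)
  cdf_at <- function(t2) {
    lam <- remeta:::q_mix_coeffs(ocd, a, t2)
    chisq_mix_cdf(lam, rep(1, length(lam)), Qobs)
  }
  expect_lt(abs(cdf_at(bj$lower) - 0.975), 1e-6)
  expect_lt(abs(cdf_at(bj$upper) - 0.025), 1e-6)
})

test_that("BJ collapses to Q-profile when all mixture coefficients are equal", {
  # balanced studies with identical variances: eigenvalues all equal, so the
  # mixture is a scaled chi-square and the inversion is the Q-profile
  y <- c(0.1, 0.5, 0.9, 0.3, 0.7, 1.2)
  r <- effect_records(y, rep(0.08, 6), rep(25L, 6), rep(25L, 6), "SMD")
  bj <- ci_bj(r)
  qp <- ci_q_profile(r)
  expect_lt(abs(bj$lower - qp$lower), 1e-4)
  expect_lt(abs(bj$upper - qp$upper), 1e-4)
})

test_that("Jackson's inversion with inverse-variance weights is the BJ machinery", {
  ocd <- ocd_records()
  bj <- ci_bj(ocd)
  viaj <- remeta:::ci_mix_inversion(ocd, 1 / ocd$variance, 0.95, "J")
  expect_equal(viaj$lower, bj$lower, tolerance = 1e-8)
  expect_equal(viaj$upper, bj$upper, tolerance = 1e-8)
})

test_that("profile-likelihood interval brackets the maximizing value", {
  r <- toy_smd(K = 10, seed = 3, n = 40, tau2 = 0.6)
  for (ty in c("reml", "ml")) {
    pl <- ci_profile_likelihood(r, type = ty)
    lp <- remeta:::loglik_profile(r, restricted = ty == "reml")
    opt <- optimize(lp, c(0, 5), maximum = TRUE, tol = 1e-10)
    t2hat <- if (lp(0) >= opt$objective) 0 else opt$maximum
    expect_gte(t2hat, pl$lower - 1e-8)
    expect_lte(t2hat, pl$upper + 1e-8)
    # endpoints satisfy the likelihood-ratio equation
    crit <- qchisq(0.95, 1)
    if (pl$lower > 0)
      expect_lt(abs(2 * (max(opt$objective, lp(0)) - lp(pl$lower)) - crit),
                1e-6)
    expect_lt(abs(2 * (max(opt$objective, lp(0)) - lp(pl$upper)) - crit),
              1e-6)
  }
})

test_that("corrected-moment intervals reduce to Q-profile for large studies", {
  # MD: gamma ~ 0
  K <- 6
  set.seed(20)
  y <- rnorm(K, 0, 0.5)
  recs <- do.call(rbind, lapply(1:K, function(i)
    md_effect(arm_summary(10^6, y[i], 1), arm_summary(10^6, 0, 1), study = i)))
  attr(recs, "measure") <- "MD"; class(recs) <- c("effect_records", "data.frame")
  wt <- ci_wt(recs); qp <- ci_q_profile(recs)
  expect_lt(abs(wt$lower - qp$lower), 1e-4)
  expect_lt(abs(wt$upper - qp$upper), 1e-4)

  # SMD: corrections -> 0 with n
  set.seed(23)
  g <- rnorm(K, 0.5, 0.03)
  big <- effect_records(g, 2 / 3000 + 1e-5 * g^2, rep(1500L, K),
                        rep(1500L, K), "SMD")
  kq <- ci_kdb(big); qq <- ci_q_profile(big)
  expect_lt(abs(kq$lower - qq$lower), 1e-4)
  expect_lt(abs(kq$upper - qq$upper), 1e-4)
})

test_that("matched point estimates nest inside their own intervals", {
  ocd <- ocd_records()
  mp <- tau2_mp(ocd)$estimate
  qp <- ci_q_profile(ocd)
  expect_true(qp$lower <= mp && mp <= qp$upper)

  md <- toy_md(K = 8, seed = 5, tau2 = 0.6)
  wtp <- tau2_wt(md)$estimate
  wtc <- ci_wt(md)
  if (wtp > 0 && wtc$lower > 0)
    expect_true(wtc$lower <= wtp && wtp <= wtc$upper)

  kdbp <- ocd_kdb()$point$estimate
  kdbc <- ocd_kdb()$ci
  expect_true(kdbc$lower <= kdbp && kdbp <= kdbc$upper)
})

test_that("intervals truncate cleanly at zero on homogeneous data", {
  h <- homog_records()
  qp <- ci_q_profile(h)
  expect_equal(qp$lower, 0)
  expect_equal(qp$upper, 0)
  expect_equal(qp$boundary_note, "degenerate_zero")
  expect_warning(ci_q_profile(effect_records(c(0.1, 0.9), c(0.05, 0.08),
                                             c(20, 20), c(20, 20), "SMD")),
                 "two studies")
})
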