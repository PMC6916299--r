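# shared fixtures and memoized expensive fits

ocd_records <- local({
  rec <- NULL
  function() {
    if (is.null(rec))
      rec <<- read_dataset(system.file("extdata", "ocd_smd.csv",
                                       package = "remeta"),
                           "effect_level", "SMD")
    rec
  }
})

# the corrected-moment SMD machinery is quadrature-heavy; fit once
ocd_kdb <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- ocd_records()
      cache <<- list(point = tau2_kdb(rec),
                     ci = suppressWarnings(ci_kdb(rec)))
    }
    cache
  }
})

# small deterministic MD set with arm SDs (for WT/CDL paths)
toy_md <- function(K = 5, seed = 42, n = 20, q = 0.5,
                   s2T = 1, s2C = 1, tau2 = 0.3) {
  cfg <- sim_config("MD", K = K, n = n, q = q, effect = 0, tau2 = tau2,
                    sigma2_treat = s2T, sigma2_control = s2C, seed = seed)
  simulate_md(cfg, 1)
}

toy_smd <- function(K = 5, seed = 7, n = 20, q = 0.5, delta = 0.5,
                    tau2 = 0.3) {
  cfg <- sim_config("SMD", K = K, n = n, q = q, effect = delta,
                    tau2 = tau2, seed = seed)
  simulate_smd(cfg, 1)
}

# homogeneous records: identical estimates, Q = 0
homog_records <- function(K = 6) {
  effect_records(rep(0.4, K), rep(0.05, K), rep(30L, K), rep(30L, K), "SMD")
}

expect_close <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
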