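---
title: "Corrected-moment estimation of between-study variance for MD and SMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corrected-moment estimation of between-study variance for MD and SMD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remeta)
```

## The model

Each of $K$ two-arm studies contributes an effect estimate
$\hat\theta_i$ with estimated within-study variance $v_i^2$.  The
random-effects model places

$$\hat\theta_i \sim N(\theta_i,\ \sigma_i^2), \qquad
  \theta_i \sim N(\theta,\ \tau^2),$$

so that marginally $\hat\theta_i \sim N(\theta, \sigma_i^2 + \tau^2)$.
Two effect measures are supported.  For the mean difference (MD),
$y_i = \bar x_{iT} - \bar x_{iC}$ and
$v_i^2 = s_{iT}^2/n_{iT} + s_{iC}^2/n_{iC}$; the estimate and its
estimated variance are independent.  For the standardized mean
difference (SMD) we use Hedges's $g$,
$g_i = J(m_i)(\bar x_{iT}-\bar x_{iC})/s_i$ with pooled SD $s_i$,
$m_i = n_i - 2$ and the exact gamma-ratio correction factor $J(m)$
(`hedges_j()`, computed with log-gamma differences rather than the
$1 - 3/(4m-1)$ shorthand, whose error only drops below $0.002$ once
$m \ge 5$).  Here the estimated variance is a deterministic function of
$g_i$ itself, which couples the weights to the estimates and is the
root of most small-sample trouble for SMD meta-analysis.

## Why corrected moments

Every classical moment estimator of $\tau^2$ (DerSimonian–Laird,
Mandel–Paule, Jackson) equates Cochran's
$Q(\tau^2) = \sum_i w_i(\tau^2)(\hat\theta_i - \bar\theta_w)^2$,
$w_i(\tau^2) = 1/(v_i^2+\tau^2)$, to an expectation derived as if the
weights were fixed constants — under which $E[Q] = K-1$ at the truth.
But the $v_i^2$ are estimates.  Their sampling variability inflates
$E[Q]$ for MD and typically *deflates* it for SMD, and the error decays
only like $1/n$.  The corrected-moment estimators replace $K-1$ by an
effect-measure-specific expectation:

* **MD (Welch-type and corrected DL).**  With
  $\gamma_i = \hat\sigma_{iT}^4/(n_{iT}^2 f_{iT}) +
  \hat\sigma_{iC}^4/(n_{iC}^2 f_{iC})$ (half the variance of $v_i^2$),
  $W = \sum w_i$, $p_i = 1 - w_i/W$, the corrected null moments are
  $$\kappa_1 = K - 1 + 2\sum_i w_i^2\gamma_i p_i^2, \qquad
    \kappa_2 = 2(K-1) + 14\sum_i w_i^2\gamma_i p_i^2 .$$
  The null law of $Q$ is approximated by a moment-matched scaled $F$
  distribution $\hat c F_{K-1,\hat f_2}$.  `tau2_wt()` solves
  $Q(\tau^2) = \kappa_1(\tau^2)$ (a Mandel–Paule analogue);
  `tau2_cdl()` is the closed-form DL analogue using the corrected
  nonnull first moment; `ci_wt()` inverts the $Q$ profile against the
  scaled-$F$ quantiles.  Because the transcription of the $\kappa_2$
  coefficient is easy to get wrong, the test suite contains a
  Monte-Carlo guard that regenerates both null moments by simulation;
  the coefficients $2$ and $14$ (same summand) reproduce the simulated
  mean and variance of $Q$ as the sample sizes grow.

* **SMD (corrected first moment).**  Hedges's $g$ has an exactly known
  sampling law: $\sqrt{\tilde n_i}\, g_i / J(m_i)$ is noncentral $t$
  with $m_i$ degrees of freedom and noncentrality
  $\sqrt{\tilde n_i}\,\delta_i$, where
  $\tilde n_i = n_{iT}n_{iC}/n_i$ is the effective sample size.  Since
  $v_i^2$ is a function of $g_i$, the expectation of $Q(\tau^2)$ under
  the random-effects model is a well-defined functional of the study
  sizes, $\delta$ and $\tau^2$, with no unknown nuisance quantities.
  `kdb_expected_q()` computes it accurately: single-study expectations
  by Gauss–Legendre quadrature on the noncentral-$t$ density (mixed
  over $\delta_i \sim N(\delta, \tau^2)$ with Gauss–Hermite nodes), and
  the weighted-mean cross term $E[U^2/V]$ by a third-order delta
  expansion, cross-checked in the tests against an exact
  Laplace-transform evaluation ($1/V = \int_0^\infty e^{-sV}\,ds$) and
  against simulation.  We deliberately compute this expectation
  accurately instead of truncating it at order $1/n$: low-order series
  expansions of the same quantity overcorrect substantially for
  small studies at moderate-to-large $\delta$ (the expansion error
  compounds across $K$ studies), which inflates the resulting
  heterogeneity estimates.  The accurate version is the one that
  matches the simulated mean of $Q$ — the package's acceptance anchor
  for this component.  `tau2_kdb()` solves
  $Q(\tau^2) = \hat E[Q(\tau^2)]$ with the inverse-variance mean as the
  plug-in for $\delta$, and `ci_kdb()` profiles $Q$ against
  chi-squared quantiles with fractional degrees of freedom
  $\hat E[Q(\tau^2)]$.

The variance model inside the SMD machinery is
$v^2(g) = 1/\tilde n + b\,g^2$.  The coefficient $b$ is inferred from
each record ($b_i = (v_i^2 - 1/\tilde n_i)/g_i^2$), so records built by
`smd_effect()` (unbiased-variance form) and records imported from
sources that used the conventional large-sample form $g^2/(2n)$ are
both handled consistently; the fallback when $g_i \approx 0$ leaves $b$
at $1/(2n_i)$, whose influence is negligible exactly there.

## Interval estimators and pooling

`ci_q_profile()` inverts the monotone, convex map
$\tau^2 \mapsto Q(\tau^2)$ against $\chi^2_{K-1}$ quantiles.
`ci_profile_likelihood()` inverts the likelihood-ratio statistic; by
default it profiles the *restricted* likelihood around the REML
estimate, which is the variant whose numbers the worked example
reproduces (`type = "ml"` gives the ordinary profile).
`ci_bj()` and `ci_jackson()` use the exact distribution of the
(generalized) $Q$ statistic — a positive linear combination
$\sum_j \lambda_j \chi^2_1$ with $\lambda_j$ the nonzero eigenvalues of
$\Sigma^{1/2} A \Sigma^{1/2}$, $A$ the weighted centering matrix and
$\Sigma = \mathrm{diag}(v_i^2 + \tau^2)$ — through `chisq_mix_cdf()`.
Jackson's statistic uses constant weights $a_i = 1/v_i$ (reciprocal
standard error); this choice is pinned by the worked example and is not
user-tunable, to keep results unambiguous.

For the overall effect, `pool_iv()` implements inverse-variance
weighting with normal intervals ($\tau^2 = 0$ giving the fixed-effect
model), `pool_hksj()` the Hartung–Knapp–Sidik–Jonkman weighted-residual
variance with $t_{K-1}$ critical values, and `pool_ssw()` the
effective-sample-size weights $\tilde n_i$ with the variance
$\sum \tilde n_i^2 (v_i^2 + \hat\tau^2)/(\sum\tilde n_i)^2$ and
$t_{K-1}$ intervals.  SSW weights contain no estimated variances, which
is what removes the downward bias that all inverse-variance estimators
of the overall SMD share.  `i_squared()` reports
$100\tau^2/(\tau^2+s^2)$ with the Higgins–Thompson typical within-study
variance $s^2 = (K-1)\sum W_i /((\sum W_i)^2 - \sum W_i^2)$; this
particular $s^2$ is a documented package choice, and the statistic's
dependence on study precisions is the reason we treat it as a
descriptive extra rather than a headline summary.

## Numerical choices

* All profile equations are solved by bracketed root finding on
  $[0, \tau^2_{\max}]$, with $\tau^2_{\max}$ grown geometrically from
  $4K\max v_i^2$; tolerance $10^{-10}$ on $\tau^2$ (the corrected-SMD
  profile uses $10^{-7}$–$10^{-8}$, matched to its quadrature
  accuracy).  Monotonicity of $Q$ guarantees uniqueness; numerically
  degenerate evaluations far to the right are treated as negative.
* REML uses the standard fixed-point iteration (at most 200 steps,
  relative tolerance $10^{-10}$, projection to zero at the boundary); a
  fine-grid search over $[0, 3]$ in the tests guards against
  local-optimum claims.
* `match_scaled_f()` solves the two moment equations in closed form; a
  finite variance needs $f_2 > 4$, and when no such solution exists the
  family falls back to a chi-squared distribution with $\kappa_1$
  degrees of freedom (flagged in the result).
* `chisq_mix_cdf()` uses the Ruben–Farebrother series (target absolute
  accuracy $10^{-8}$, working constant $\beta = 0.90625\,\lambda_{\min}$)
  with Imhof-type numerical inversion of the characteristic function as
  the alternative path and automatic fallback; the Imhof integral is
  truncated by an explicit envelope bound on its oscillatory tail.
  Both paths are unit-tested against each other and against $10^6$-draw
  Monte Carlo.
* Point estimates are truncated at zero; the untruncated value is kept
  on the result (`$untruncated`) because bias studies need it: at
  $\tau^2 = 0$ *every* nonnegative estimator has positive bias after
  truncation, so "essentially unbiased" claims are statements about the
  estimating equation, i.e. the untruncated scale.  Simulation
  summaries default to the truncated values (what a user sees) with an
  `untruncated = TRUE` switch.
* Two-study meta-analyses are accepted with a loud warning (intervals
  can be unbounded); single studies are rejected.

## The simulation harness

`sim_config()` fixes one cell of a factorial design: measure,
$K \in \{5, 10, 30\}$ (any $K \ge 2$ is accepted), total sizes $n$
(equal, or the skewed five-study patterns retrievable with
`unequal_sizes()`, repeated across $K$), control fraction
$q \in \{.5, .75\}$ with arm sizes $n_{iT} = \lceil (1-q)n_i\rceil$,
effect, $\tau^2$, and (MD) the true arm variances.  `simulate_md()`
draws per-arm sample variances as scaled chi-squares
$\sigma_{ij}^2\chi^2_{n_{ij}-1}/(n_{ij}-1)$ and effect estimates as
normals with variance
$\sigma_{iT}^2/n_{iT} + \sigma_{iC}^2/n_{iC} + \tau^2$ — the unpooled
two-arm design.  `simulate_smd()` draws $\delta_i \sim N(\delta,\tau^2)$
and then $g_i$ *directly* from its scaled noncentral-$t$ law, with
variances from the unbiased formula.  Seeding is per replicate (a
counter-based substream of the master seed), so any single replicate is
reproducible in isolation and results are invariant to how replications
are chunked.

The generator reproduces the generative models used in the estimators'
own evaluation designs — normal arms, exact $t$ sampling for $g$,
independent studies.  It does not emulate non-normal raw data,
correlated arms, selective reporting or measurement error, so green
simulation tests certify internal correctness of the estimators under
the stated model, not robustness on messy real data.

Default replication counts are desk-scale: 2,000 per configuration
(`reps` in `sim_config()`), at which the Monte-Carlo SE of a coverage
estimate at the 95% level is `mc_se_coverage(0.95, 2000)` ≈ 0.0049; the
full-scale 10,000 of a production study is a parameter, not a code
change.  The packaged checks use 2,000-replication runs for the bias
and coverage properties, 50,000 draws for generator moments, and
$10^5$–$2\times10^5$ draws for the null-moment oracles.

## Known limitations

* The corrected-moment SMD expectation costs a few seconds per fit at
  $K \sim 25$ (quadrature per study per profile step); the classical
  estimators are effectively instantaneous.
* The plug-in $\delta$ in the SMD correction is the inverse-variance
  mean at the current $\tau^2$; its own small-sample bias (a few
  percent, downward) perturbs the correction only at second order, but
  is not accounted for.
* Corrected moments are implemented for MD and SMD only; other
  measures (log odds ratio, response ratio) have different weight-
  estimate couplings and are out of scope.
* The SSW interval uses $t_{K-1}$ critical values as a pragmatic
  choice; the exact sampling distribution of the SSW estimator is not
  derived here.
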