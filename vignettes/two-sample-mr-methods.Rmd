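---
title: "Methods: two-sample Mendelian randomization from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsummary)
```

## The problem and the model

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure (here, thyroid
function measured as TSH, FT4 or TPOAb positivity per standard
deviation) on an outcome (ischemic heart disease, measured as a log odds
ratio), exploiting the random allocation of alleles at conception. In
the two-sample (separate-sample) design, the variant–exposure and
variant–outcome associations come from non-overlapping studies and only
published summary statistics are needed: for variant $j$, an exposure
effect $\hat\beta_{Xj}$ with standard error $\sigma_{Xj}$ and an outcome
effect $\hat\beta_{Yj}$ with $\sigma_{Yj}$.

A variant is a valid instrument when it is (i) associated with the
exposure, (ii) not associated with the outcome except through the
exposure (no horizontal pleiotropy), and (iii) not associated with
confounders. Under validity, each variant yields a Wald ratio
$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$ estimating the causal
effect $\theta$, with first-order (delta-method) standard error
$|\hat\beta_{Xj}|^{-1}\sqrt{\sigma_{Yj}^2 +
\hat\theta_j^2\sigma_{Xj}^2}$.

The estimators implemented, reported side by side as MR practice
recommends:

* **Fixed-effect IVW.** $\hat\theta_{IVW} = \sum_j w_j\hat\theta_j /
  \sum_j w_j$ with $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, standard
  error $(\sum_j w_j)^{-1/2}$ — equivalently, a weighted through-origin
  regression of outcome on exposure effects. First-order weights are the
  fixed-effect convention; second-order weights (adding the
  $\hat\theta_j^2\sigma_{Xj}^2$ term) are available but off by default.
* **Generalized weighted regression for correlated variants.** When
  instruments are in linkage disequilibrium (LD) with correlation matrix
  $\rho$, the IVW score is generalized to GLS with error covariance
  $\Omega_{jk} = \sigma_{Yj}\sigma_{Yk}\rho_{jk}$:
  $\hat\theta = (\beta_X^\top\Omega^{-1}\beta_X)^{-1}
  \beta_X^\top\Omega^{-1}\beta_Y$. With $\rho = I$ this reduces exactly
  to fixed-effect IVW (a unit-tested identity). $\Omega$ is factored by
  Cholesky; a non-positive-definite $\rho$ is an error that names the
  offending eigenvalue.
* **Weighted median.** The 50% point of the inverse-variance-weighted
  empirical distribution of Wald ratios (cumulative weight midpoints
  $p_j = (S_j - w_j/2)/S_m$, linear interpolation at $p = 0.5$), with
  weights from the delta-method variances. It is consistent when valid
  instruments carry more than half the weight. Its standard error is a
  seeded parametric bootstrap (default 1000 resamples) drawing
  $(\hat\beta_{Xj}, \hat\beta_{Yj})$ from independent normals at their
  stated standard errors.
* **MR-Egger.** After orienting every variant so
  $\hat\beta_{Xj} > 0$, a weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ with a free intercept (weights
  $1/\sigma_{Yj}^2$). Under the InSIDE assumption (pleiotropic effects
  independent of instrument strength) the slope estimates $\theta$ even
  when all instruments are pleiotropic; the intercept estimates the
  average directional pleiotropic effect, and an intercept p-value below
  0.05 flags directional pleiotropy.
* **Fieller confidence set** for the single-variant ratio: the exact set
  $\{\theta : (\hat\beta_Y - \theta\hat\beta_X)^2 \le
  z^2(\sigma_Y^2 + \theta^2\sigma_X^2)\}$, which is a finite interval
  when the denominator is clearly nonzero
  ($A = \hat\beta_X^2 - z^2\sigma_X^2 > 0$), the complement of an
  interval when it is not ($A < 0$, "exclusive"), and the whole line
  when the discriminant is negative. The delta-method standard error is
  always reported alongside; non-finite sets are propagated as flags,
  never forced into a standard error.
* **Cochran's Q** for heterogeneity, $Q = \sum_j w_j(\hat\theta_j -
  \hat\theta_{IVW})^2 \sim \chi^2_{m-1}$ under homogeneity, with the
  fixed-effect IVW weights.

Study-level reporting: estimates on the log-odds scale are
exponentiated to odds ratios per SD of exposure; the family-wise
Bonferroni threshold divides $\alpha$ by (outcome traits) ×
(exposures), e.g. $0.05/5/3 \approx 0.003$; and binary-outcome power
uses the normal approximation
$\mathrm{power} = \Phi(|\ln OR|\sqrt{N R^2 K(1-K)} - z_{1-\alpha/2})$
with $N$ the total case-control sample size, $K$ the case fraction and
$R^2$ the exposure variance explained by the instruments. The minimal
detectable OR is its exact inverse,
$\exp\{(z_{\mathrm{power}} + z_{1-\alpha/2}) / \sqrt{N R^2 K(1-K)}\}$;
the negligible opposite-tail term is omitted, which is what makes the
inversion exact. For the 195,055-person design (64,374 cases) this
gives a detectable OR of 1.04 per SD at $R^2 = 0.14$ and 1.07 at
$R^2 = 0.04$:

```{r power}
cfg <- power_config(n_total = 195055, n_cases = 64374, r2 = 0.14)
round(detectable_or(cfg), 2)
round(detectable_or(power_config(195055, n_cases = 64374, r2 = 0.04)), 2)
```

## Instrument selection

Candidate instruments pass three filters, each recorded with a reason
so that the final instrument accounting can be audited line by line:

1. **Genome-wide significance**: retain $p < 5\times10^{-8}$ (strict
   inequality).
2. **LD pruning**: for every pair with $r^2 > 0.7$ the member with the
   larger p-value is discarded. Pairs are processed in descending $r^2$
   with lexicographic tie-breaks, and exclusions cascade (an excluded
   variant cannot exclude others); this deterministic order makes the
   retained set reproducible and row-order invariant. Variants below
   the $r^2$ cut are retained and their correlation can be passed on to
   the GLS estimator.
3. **Pleiotropy exclusion lists**: variants with known cross-trait
   associations are supplied by the user (curated from cross-reference
   services); the pipeline always evaluates the analysis both with and
   without them, the paired reporting convention.

Variants absent from the outcome panel are recovered through a
user-supplied proxy map where possible and otherwise recorded as
unavailable. Instrument strength is summarized per variant by
$F = (\hat\beta_X/\sigma_X)^2$, the squared z-score — the standard
two-sample approximation; the alternative $R^2$-based form
$F = R^2(n-2)/(1-R^2)$ is provided as `variant_f_statistic_r2()`.

## Harmonization

Exposure and outcome tables are intersected on rsID (no positional
fallback: the consortium inputs this design mirrors are rsID-keyed) and
the outcome effect re-oriented onto the exposure's effect allele,
handling allele swaps, strand complements, or both; incompatible allele
pairs are dropped with reason. Palindromic variants (A/T, C/G) carry no
strand information in their labels, so by default they are dropped
(`palindrome_policy = "drop"`, the conservative choice since a silent
strand error flips the sign of an effect); `"infer-by-eaf"` orients them
by allele-frequency concordance when both frequencies lie outside
$0.5 \pm 0.08$ (`eaf_window`). Allele frequency is used only for this
orientation; variants with missing frequency are retained unless they
are palindromic under `"infer-by-eaf"`. Harmonization is idempotent and
invariant to wholesale re-encoding of the outcome table, both
property-tested.

## The synthetic-data generator

Because the real consortium downloads cannot be redistributed, every
stage is exercised on a generator that emits the same file formats with
the statistical structure the estimators assume, on the
summary-statistic scale directly (no individual-level genotypes — the
pipeline only ever sees summary statistics):

$$\gamma_j \sim |N(0, \gamma_s^2)|,\quad
\hat\beta_{Xj} = \gamma_j + \varepsilon_{Xj},\quad
\hat\beta_{Yj} = \theta\gamma_j + \alpha_j + \varepsilon_{Yj},$$

with noise at the stated standard errors (drawn jointly with
correlation $\rho$ when an LD matrix is supplied, independently between
the two sides as the separate-sample design implies), and pleiotropy
$\alpha_j$ by regime: `none`; `balanced` (mean zero); `directional`
(mean $\bar\alpha \ne 0$, independent of $\gamma_j$ — InSIDE holds); or
`inside_violating` ($\alpha_j$ correlated with $\gamma_j$). True
effects are half-normal, i.e. each variant is oriented to its
exposure-increasing allele — the standard instrument convention, and
the regime in which directional pleiotropy biases ratio estimators in
its own direction. Emitted p-values are exactly the two-sided normal
p implied by beta/se, so the significance filter behaves correctly on
synthetic tables, and the outcome table is emitted in random per-variant
allele orientations so harmonization is genuinely exercised.

Default scales are fixed to emulate a thyroid-function-style design:
$\sigma_X = 0.006$ per SD (a quantitative-trait GWAS of ~26k people),
$\gamma_s = 0.046$ so the mean per-variant $F = 1 +
(\gamma_s/\sigma_X)^2 \approx 60$, matching the reported instrument
strengths near 59–61, and $\sigma_Y = 0.012$ on the log-odds scale (a
~195k case-control panel). Scenario presets mirror the four analysis
arms with $m = 20, 22, 5, 2$ instruments ($\gamma_s = 0.14$,
$\sigma_X = 0.025$ for the 2-variant arm, giving $F \approx 33$).

What the generator does **not** emulate: realistic allele-frequency
spectra and LD beyond block-exchangeable correlation, winner's-curse
selection of the discovery GWAS, sample overlap between the two
samples, and non-collapsibility of the odds ratio. Passing tests
therefore demonstrate the estimators' statistical properties under
their assumed model, not robustness to those real-data features.

Two consequences of the half-normal effect distribution are worth
knowing. First, it places mass near zero, so in pipeline runs a
sizeable fraction of simulated variants legitimately falls below
genome-wide significance and is partitioned out — simulated instrument
counts are therefore checked against the emitted p-values, not the
nominal $m$. Second, near-zero true effects let sampling noise flip the
observed sign of $\hat\beta_X$; the MR-Egger orientation step then
flips those variants' pleiotropic effects too, attenuating the mean
intercept below the generating $\bar\alpha$ (about 0.016 recovered for
a generating 0.02 at $m = 20$, $F \approx 60$). This is a property of
the estimator under weak instruments, not an implementation artifact,
and the calibration tests pin it against an independent
re-implementation of the same model.

## Numerical and inferential choices

* **Egger dispersion.** Coefficient standard errors use unit residual
  dispersion by default, consistent with the fixed-effect weighting
  used everywhere else in the analysis; under homogeneity this makes
  the intercept z-statistic exactly standard normal, so its p-value is
  exactly calibrated (verified by simulation). A multiplicative
  overdispersion option (`dispersion = "estimated"`, scaling by
  $\max(1, \hat\sigma)$) and a Student-t reference (`reference = "t"`)
  are provided for the random-effects practice common elsewhere.
* **P-values** for all pooled estimators use the standard-normal
  reference on estimate/SE.
* **Fieller degenerate geometry.** $A = 0$ (a boundary case of measure
  zero) degenerates to a half-line and is classified as such; a
  negative discriminant can only occur with $A \le 0$ (the set always
  contains the point ratio), yielding the whole line.
* **LD pruning ties** (equal $r^2$, equal p) break lexicographically on
  variant id so results never depend on input order.
* **Weighted-median edge cases**: a cumulative midpoint grid that does
  not bracket 0.5 returns the corresponding extreme ratio; at least 3
  variants are required, as for Egger.
* **Seeds.** Every stochastic component (generator, bootstrap,
  pipeline) takes an explicit seed; seeded routines restore the
  caller's RNG state so experiment loops stay independent. Pipeline
  analyses derive per-analysis sub-seeds from the master seed, so
  results do not depend on analysis order.
* **Problem sizes** used by the verification suite: oracle-equivalence
  checks on 100 random 4–8-variant instances at $10^{-10}$ tolerance;
  null calibration of Cochran's Q and the Egger intercept on 2000
  replicates of the 20-variant design; IVW coverage at $\theta = 0.2$
  on 1000 replicates; pleiotropy bias decomposition on 1000 replicates;
  weighted-median breakdown on 2×300 replicates. These sizes put
  binomial Monte-Carlo error well inside the asserted bands while
  keeping the default test run in tens of seconds.

## Limitations

Beyond the generator's scope above: no random-effects IVW, mode-based
estimators, multivariable MR, SIMEX/I² correction for Egger, automated
pleiotropy discovery, distance-based clumping, or remote proxy/LD
lookup — exclusion lists, proxy maps and LD matrices are explicit
inputs, which keeps every selection decision auditable. The power
formula is the binary-outcome normal approximation; continuous-outcome
power is out of scope. MR estimates from case-control summary data are
best read as tests of causation rather than precise effect sizes.
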