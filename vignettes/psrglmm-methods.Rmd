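---
title: "Pseudo-response mixed-model genome scans for non-normal traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-response mixed-model genome scans for non-normal traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psrglmm)
```

## The model

Many traits mapped in crops and livestock are not normally distributed:
presence/absence of a mutant phenotype, healthy offspring out of a litter,
counts of stillbirths, graded coat types. `psrglmm` maps such traits under a
generalized linear mixed model with a polygenic random effect,

$$\eta = \zeta^{-1}(\mu) = X\beta + Z\gamma, \qquad
  \gamma \sim N(0, \sigma_\gamma^2 K),$$

where $\zeta^{-1}$ is the link (logit for binary/binomial, log for Poisson,
cumulative logit for ordinal, identity for gaussian), $X\beta$ holds the
intercept, optional covariates and the candidate marker, and $K$ is a
marker-derived kinship matrix that absorbs population structure and polygenic
background.

The estimator is the *pseudo-response* (working-variable) linearization.
A first-order expansion of the mean function at the current linear predictor
$\tilde\eta$, with $\Delta = \partial\mu/\partial\eta$ evaluated there, turns
the observations into

$$\tilde p = \Delta^{-1}\,(y - \mu(\tilde\eta)) + \tilde\eta,$$

a quantity on the linear-predictor scale that follows, to this order, an
ordinary linear mixed model $\tilde p = X\beta + Z\gamma + \varepsilon$ with
working residual covariance $R = \sigma_\varepsilon^2\,\Delta^{-1}\Sigma
\Delta^{-1} = \sigma_\varepsilon^2 W^{-1}$, where $\Sigma(\mu)$ is the
family's variance function and $W = \Delta \Sigma^{-1} \Delta$ the working
weight. The residual scale $\sigma_\varepsilon^2$ is estimated freely rather
than pinned at its theoretical value of 1 for discrete families; the fitted
value sits near 1 but not exactly there, and the downstream heritability
summaries use the estimate.

Variance components maximize the restricted likelihood of the linearized
model,

$$L_R(\sigma_\gamma^2) = -\tfrac12 \ln|V| - \tfrac12 \ln|X'V^{-1}X|
  - \tfrac12 (\tilde p - X\hat\beta)' V^{-1} (\tilde p - X\hat\beta),
  \qquad V = \sigma_\gamma^2 ZKZ' + \sigma_\varepsilon^2 W^{-1}.$$

### The doubly iterative algorithm

`fit_glmm()` alternates two inner loops:

1. **Linearization (iterative BLUP).** At fixed
   $(\sigma_\gamma^2, \sigma_\varepsilon^2)$, rebuild $\tilde p$ and $W$ at
   the current $\tilde\eta$, solve the mixed-model equations for
   $(\hat\beta, \hat\gamma)$, update $\tilde\eta$; repeat until the maximum
   relative change in $\tilde\eta$ falls below `tol_inner1` ($10^{-6}$).
2. **REML.** On the current pseudo data, profile $\sigma_\varepsilon^2$ out
   in closed form and maximize $L_R$ over the ratio
   $\lambda = \sigma_\gamma^2/\sigma_\varepsilon^2$.

The outer loop alternates 1 and 2 until the variance components stabilize.
For the identity link the linearization is exact ($\tilde p \equiv y$), so a
gaussian fit is a single REML solve and the whole machinery collapses to the
standard linear mixed model — a reduction asserted in the test suite.

### Ordinal traits

A trait with $C$ ordered categories is handled on the cumulative-logit
(proportional odds) scale: each individual carries $C-1$ linear predictors
$\eta_{ic} = \alpha_c - (x_i'\beta + \gamma_i)$ with increasing thresholds
$\alpha_1 < \dots < \alpha_{C-1}$, and the pseudo response is built from the
cumulative indicators $u_{ic} = I(y_i \le c)$, whose covariance block
$\mathrm{cov}(u_c, u_{c'}) = \pi_{\min}(1-\pi_{\max})$ makes $W$
block-diagonal rather than diagonal. The sign convention means a positive
marker effect shifts probability mass toward higher categories; a published
analysis with the opposite convention would show flipped signs. With $C = 2$
the machinery degenerates to the binary model exactly (another tested
reduction). The $C-1$-fold row expansion makes ordinal fits the most
expensive family, as in any multivariate working model.

## The four genome scans

* **`glm`** — per-marker generalized linear model with no polygenic term
  (via `stats::glm`/`MASS::polr`). The naive baseline: under polygenic
  structure its false-positive rate is badly inflated, which the calibration
  tests demonstrate.
* **`glmm`** — the exact route: the full doubly iterative fit per marker,
  variance components re-estimated each time.
* **`p3d`** — variance components estimated once under the null model and
  frozen; each marker re-runs only the linearization loop.
* **`psr`** — the fastest route and the package's namesake: the *null*
  model's converged pseudo response, working weights and variance components
  are all frozen, the whitened kinship is factorized once, and each marker
  costs one generalized least-squares solve. This is exactly a quantitative
  -trait (EMMAX-style) scan of the pseudo response, which is why its cost is
  within a small factor of a gaussian scan regardless of the family.

The P3D/PSR distinction matters: P3D relinearizes per marker at fixed
variance components, PSR never relinearizes. The expected cost ordering
(psr < p3d < glmm) is reproduced on synthetic data by
`scripts/acceptance.R`.

Wald statistics are $(\hat\beta/\mathrm{se})^2$ against the 1-df chi-square;
multiple testing uses the Bonferroni threshold
$\chi^2_1(1 - \alpha/m)$, with monomorphic markers excluded from $m$ and
reported as sentinel records.

### QTL heritability

Per-peak summaries regress the reporting method's converged pseudo response
on the marker: with `MS_QTL` the 1-df model mean square and `MS_E` the
residual mean square,

$$\hat\sigma^2_{QTL} = \max\!\left\{0, \frac{MS_{QTL} - MS_E}{n-1}\right\},
\qquad
\hat h^2_{QTL} = \frac{\hat\sigma^2_{QTL}}{\hat\sigma^2_{QTL} + MS_E}.$$

The $(n-1)$ divisor was validated against an independent ANOVA computation
(`anova(lm(...))`) in the tests. Because each method converges to its own
pseudo response, the mean squares — and therefore the reported heritability —
are method-specific. This heritability lives on the linear (link) scale, not
the observed scale.

## Numerical design

* **Rotated REML.** With $S = W^{1/2}$, the transformed covariance is
  $\sigma_\varepsilon^2(\lambda H + I)$ with $H = SKS = UDU'$; one symmetric
  eigendecomposition per REML step makes every candidate $\lambda$ an
  $O(Np)$ weighted least-squares solve. When the kinship carries its marker
  factor $K = PP'$ (attached by `kinship_from_markers()`) and $m$ is well
  below $0.8\,n$, the same basis comes from the $m \times m$ Gram matrix of
  $SP$ — a large saving for dense scans at modest marker panels — and the
  fixed-variance solves use the Woodbury identity. Both representations are
  exact and are tested equal to a naive dense evaluation of $L_R$ to
  $10^{-8}$ and to a dense Henderson solve to $10^{-10}$.
* **$\lambda$ search.** Brent localization on $\ln\lambda$ over
  $[\ln 10^{-6}, \ln 10^{6}]$, then a root solve of the analytic REML score.
  The polish step exists because the profiled criterion is flat to machine
  precision near its optimum, so derivative-free search alone localizes
  $\lambda$ only to about $\sqrt{\epsilon}$; the score retains full
  precision. Boundary optima (pure-noise data) are detected by comparing the
  endpoints.
* **Outer convergence** is declared when the variance components change by
  less than `tol_outer` ($10^{-6}$) *relative to the total variance* — the
  scale-free form stays meaningful when one component sits at the boundary
  near zero. A tighter tolerance buys nothing: the linearization error of
  the pseudo-likelihood itself dominates far above $10^{-6}$, and pushing
  the alternation further only repeats factorizations.
* **Clamping.** Means are clamped to $[10^{-8}, 1-10^{-8}]$ (the
  linearization divides by $\Delta$) and linear predictors to $\pm 30$;
  fits that hit the clamp are flagged. Perfect co-segregation of a marker
  with a binary trait — the classic separation failure, where the Wald
  statistic collapses toward zero while the effect estimate diverges — is
  reported with a `separation`/`clamped` note rather than an error.
* **Kinship ridge.** Dense kinships get $K + 10^{-6}\bar{k}\,I$ before
  factorization; factor-backed kinships need no ridge since $PP'$ is
  positive semi-definite by construction.
* **Dual engines.** The univariate factor path also exists as compiled code
  (RcppArmadillo); the R reference path remains the definition, and the test
  suite holds the two equal to $10^{-6}$ or better across families.

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws RIL-like ($\pm 1$) or F2-like ($-1/0/+1$) bin
genotypes as a two-state Markov chain along each chromosome
(`switch_prob = 0.05` per interval by default), giving the long LD blocks
typical of bin-map populations. The switch probability controls the
effective dimensionality of the kinship: at dense maps a realistic RIL has
only one to three crossovers per chromosome, so emulating, say, 1619 bins
over 12 chromosomes calls for `switch_prob` near 0.015. This matters beyond
realism — when the marker panel is dense relative to $n$ *and* the map
recombines too freely, the kinship approaches full rank and a binary trait
can be quasi-separated through the polygenic term, driving the
pseudo-likelihood variance ratio to its search bound (such fits are flagged,
and excluded from the bias summaries). The $\pm 1$ coding at allele frequency 1/2
gives each marker unit variance, so a liability effect $\beta_q$ with unit
polygenic variance and a logistic observation step implies

$$h^2_{QTL} = \frac{\beta_q^2}{\beta_q^2 + 1 + \pi^2/3},$$

about 0.10 at $\beta_q = 0.7$ and 0.18 at $\beta_q = 1.0$ — the effect sizes
used by the bias study. `simulate_liability()` adds
$\gamma \sim N(0, \sigma_\gamma^2 K)$ and optional gaussian noise;
`liability_to_trait()` converts to Bernoulli draws (or a deterministic
threshold), binomial counts, Poisson counts on a standardized log scale, or
quantile-cut ordinal categories.

The generator does *not* emulate: allele-frequency spectra away from 1/2,
coalescent-realistic LD decay, pedigree or admixture structure, missing-data
patterns, or genotyping error. Passing calibration and power checks on these
synthetic populations therefore demonstrates correctness of the estimator
under its own assumptions, not robustness to everything real data can do.

## Study sizes, findings and limitations

The replicated studies in the test suite run at desk scale, chosen so the
whole suite completes in minutes while keeping Monte-Carlo standard errors
small enough for the assertions: calibration at $n = 200$, $m = 100$, 200
replicates; bias at 100 replicates; power parity over six effect sizes
(0.25–1.0, including 0.7 and 1.0) at $n = 150$, $m = 40$, 200 replicates with
positives counted within a 5-bin window on the causal chromosome.

Two findings from those studies are worth stating plainly:

* **Effect estimates are attenuated; the variance component is not.** For
  binary traits the causal-marker effect comes out below its true value
  (about 5% low at `n = 200` with a 100-marker kinship, and further below
  with denser panels), and the attenuation grows with the QTL size — users
  who need unbiased effect sizes at detected loci should refit those few
  markers with a marginal-likelihood or Bayesian method. In this simulator
  most of the attenuation traces to candidate-in-kinship shrinkage (part of
  the marker's own signal is absorbed by the polygenic BLUP): regenerating
  the causal marker independently of the kinship panel removes nearly all of
  it. The polygenic variance estimate, by contrast, shows *no* measurable
  downward bias here — the severe downward bias of pseudo-likelihood
  variance components documented for sparse-cluster binary designs does not
  materialize under a smooth, dense RIL kinship at these sample sizes, and
  the right-skew of the REML ratio if anything pushes its mean slightly
  above the truth. Replicates whose variance ratio runs into the search
  bound (quasi-separation through the polygenic term) are flagged and
  excluded from the bias summaries, which report how many fits were kept.
* **Proximal contamination is visible at small marker panels.** The kinship
  is built from *all* markers, including the candidate being tested. With
  only $m = 100$ markers each candidate carries about $1/m$ of the polygenic
  variance itself; re-estimating the variance components per marker (the
  exact `glmm` route) then releases part of that share into the fixed effect
  and inflates the type-I error to about 0.065 at the nominal 0.05 — an
  effect we verified is absent (rates return to ≈0.05) when the same
  scenario is run with $K$ built from an 800-marker panel, and equally
  present for gaussian traits, so it is a property of candidate-in-kinship
  REML re-estimation, not of the linearization. P3D and PSR, which freeze
  the null variance components, stay calibrated even at $m = 100$. At
  realistic panel sizes (the motivating datasets use 1619 bins to 216 k
  SNPs) the per-marker share is negligible. Leave-one-chromosome-out
  kinships would remove the effect entirely but are deliberately not
  implemented, to keep the kinship definition identical across methods.

Other known limitations: no score tests or saddlepoint corrections for
extreme case-control imbalance; Bonferroni is the only multiple-testing
control; families beyond {gaussian, binary, binomial, Poisson, ordinal} are
not provided, though a family is just a closed set of mean/derivative/
variance callables and slots in without touching the solvers.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_trait(
  n = 278, m = 400, qtl_index = 200, beta_q = 1, sigma_g2 = 1,
  family = "binary", seed = 42
)
scan <- psr_scan(sim$pheno, sim$geno, sim$kinship, method = "psr")
scan_qtl_summary(scan, sim$geno)
autoplot(scan)
```

The command-line interface wraps the same functions
(`inst/cli/psrglmm scan --geno ... --pheno ... --family binary --method psr
--out scan.tsv`), writing the scan TSV plus a JSON sidecar with the
null-model variance components, thresholds and flags.
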