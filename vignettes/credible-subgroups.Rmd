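---
title: "Credible subgroup pairs for binary trial endpoints: model, method and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Credible subgroup pairs for binary trial endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Randomised trials report average treatment effects, but patients differ: a
trial-wide null can hide a minority of profiles that benefit and another that
is harmed. Classical subgroup analyses test one covariate at a time and
multiply type-I error across tests. `credpair` implements the credible
subgroups approach for a binary endpoint: instead of testing prespecified
subgroups, it estimates a *pair* of sets in covariate space that bracket the
unknown benefiting subgroup with a joint posterior guarantee, accounting for
the multiplicity of testing a hypothesis at every covariate point.

The motivating setting is a large lifestyle-intervention trial in type 2
diabetes with a composite cardiovascular endpoint and four baseline
covariates: subjective general health (SF-36 GH), age, sex, and diabetes
control (HbA1c). The restricted subject-level data are not redistributable,
so the package ships a synthetic-cohort generator that emulates that trial's
published covariate moments and posterior coefficient estimates; everything
downstream is tested against that stated world.

## Model

For subject $i$ with covariate vector $x_i$ (prognostic) and $z_i$
(predictive; here the same four covariates plus a constant), treatment
indicator $t_i \in \{0,1\}$ and event indicator $Y_i$:

$$Y_i \mid \eta_i \sim \mathrm{Bernoulli}\big(\mathrm{logit}^{-1}(\eta_i)\big),
\qquad \eta_i = x_i'\beta + t_i\, z_i'\gamma.$$

Continuous covariates are standardized (sample mean 0, sd 1, $n-1$
denominator) on the complete-case analysis sample; sex is coded 1 = male.
Priors are independent normals: $\beta_j \sim N(0, 1000)$ (vague, preserving
observed prognostic relationships) and $\gamma_j \sim N(0, 1)$ (sceptical of
large treatment-effect heterogeneity, while still allowing strong data
evidence to dominate).

The personalised treatment effect at profile $z$ is reported
benefit-positive on the log-odds scale,

$$\Delta(z) = -\,z'\gamma,$$

so positive values mean reduced odds of the harmful event; the threshold
$\delta$ defaults to 0 to capture benefits of any magnitude. A
risk-difference scale,
$\mathrm{logit}^{-1}(z'\beta) - \mathrm{logit}^{-1}(z'\beta + z'\gamma)$,
is available as a secondary option (with the same covariates acting
prognostically and predictively).

## Posterior computation

The posterior is sampled with Pólya-Gamma data augmentation: each
observation receives a latent $\omega_i \sim \mathrm{PG}(1, \eta_i)$, after
which the ten coefficients have a conjugate multivariate-normal full
conditional. The PG(1, z) draws use Devroye's alternating-series rejection
sampler, implemented in C++ against R's RNG so chains are bit-reproducible
under `set.seed()`. Defaults follow the reference analysis: one chain,
10,000 retained draws after 1,000 burn-in, zero initialization. A
random-walk Metropolis sampler (proposal covariance from the penalized mode,
scaled by $2.38/\sqrt{d}$) sits behind the same interface as a fallback and
as a cross-check; with proper priors both remain well defined even under
complete separation.

Passing `dm = NULL` to `sample_posterior()` runs the no-data limit, in which
the Gibbs draws are exact prior draws — this is how the test suite verifies
prior handling. Diagnostics report per-coefficient autocorrelation (to lag
50 by default) and effective sample size by Geyer's initial-positive-sequence
rule, capped at the number of draws.

## From draws to subgroups

Over a covariate grid $\{z_j\}$ the package computes pointwise posterior
means $\hat\mu_j$ and sds $\hat\sigma_j$ of $\Delta(z_j)$, the per-draw
sup-standardized deviation

$$W^{(k)} = \max_j \frac{|\Delta^{(k)}(z_j) - \hat\mu_j|}{\hat\sigma_j},$$

and the band multiplier $c$ as the empirical level-$(1-\alpha)$ quantile of
$\{W^{(k)}\}$ (inverted-CDF convention, so the discrete guarantee is
$\ge 1-\alpha$). The simultaneous band is
$[\hat\mu_j - c\hat\sigma_j,\; \hat\mu_j + c\hat\sigma_j]$; the exclusive
credible subgroup $D$ collects points with lower bound above $\delta$, the
inclusive subgroup $S$ those with upper bound above $\delta$, and the
defining property $P(D \subseteq B \subseteq S \mid \text{data}) \ge
1-\alpha$ holds by construction for the benefiting set
$B = \{z : \Delta(z) > \delta\}$. `bracket_probability()` recomputes that
probability by direct Monte-Carlo enumeration over the draws — it is the
oracle for the guarantee, not its source. The signed maximum-credible-level
surface inverts the construction: because $c(\ell)$ is non-decreasing in
$\ell$, membership of $D(\ell)$ or $S^c(\ell)$ reduces to comparing
$c(\ell)$ with each point's standardized margin, so the whole surface costs
a single pass over the draws.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| prognostic prior variance | 1000 | log-odds² | vague; preserves covariate-endpoint relationships |
| predictive prior variance | 1 | log-odds² | sceptical of large heterogeneity |
| retained draws / burn-in | 10,000 / 1,000 | iterations | reference-analysis configuration; PG mixing is near-immediate |
| threshold $\delta$ | 0 | log-odds | capture benefit of any magnitude |
| credible levels | 0.5, 0.65, 0.8 | probability | the levels the reference analysis reports |
| grid resolution | 20 per continuous axis | points | $2\cdot20^3 = 16{,}000$ points; the original evaluation grid is unstated |
| grid span | 1st-99th percentile | raw units | avoids extrapolating the band into empty covariate space |
| level grid (inversion) | 0.001 steps | probability | resolution of the signed max-level surface |

## The synthetic world

`generate_cohort()` draws age, SF-36 GH and HbA1c as independent normals and
sex and treatment as Bernoullis, using the published entire-sample moments
(age 58.9 (6.8) y; 41% male; HbA1c 7.3 (1.2)%; SF-36 GH 47.2 (8.9); 1:1
allocation), then generates events from the logistic model with the published
posterior means as default truth. Choices a user should know:

* **Independence.** Only marginal moments are published, so covariates are
  generated independently; a correlation hook (`corr =`) exists for
  sensitivity work. Real cohorts correlate general health with HbA1c, so a
  green test here does not establish behaviour under collinearity.
* **Standardization scale.** Events are generated on covariates standardized
  *within the generated sample*, exactly as the analysis model standardizes,
  so generating coefficients and fitted coefficients share a scale and
  parameter recovery is well defined.
* **Unbounded normals.** No truncation to trial eligibility windows
  (eligibility is not published); tails slightly exceed a real cohort's.
* **Missingness.** Injected missingness (`inject_missingness()`) blanks
  covariates completely at random; it exercises the complete-case filter,
  not any informative-missingness scenario.

What a green suite establishes: the sampler targets the stated posterior,
the band/classification machinery delivers its bracketing guarantee on data
*from this generator*, and the pipeline is deterministic. What it does not:
agreement with the restricted original data, behaviour under correlated or
informatively missing covariates, or model misspecification.

## Numerical choices

* **sd floor.** Grid points with pointwise sd below $10^{-12}$ get a
  zero-width band (lower = upper = mean) and are excluded from the sup in
  $W$, avoiding 0/0 while leaving the band elsewhere untouched.
* **Quantile convention.** Type-1 (inverted CDF) for the band multiplier:
  reproducible, and the discrete coverage guarantee is exact.
* **Two-sided bands.** Both $D$ and $S^c$ are read off one symmetric band;
  one-sided constructions are out of scope.
* **Streaming.** Band statistics are computed in draw blocks (three passes:
  mean, two-pass sd, sup deviations), so 10,000 draws on 50,000+ points
  never materialize the full matrix; the two-pass variance also keeps the
  streaming result bit-comparable to a dense textbook computation.
* **Ties and ESS.** Row maxima use a deterministic first-tie rule (no RNG
  consumption); ESS truncates at the first non-positive autocorrelation pair
  sum and is capped at the draw count.
* **Degenerate inputs.** Constant covariates stop standardization with an
  error; constant chains stop `diagnostics()`; complete separation is
  handled by the proper priors.

## Open design decisions, resolved

* **Sampler choice.** The reference analysis names a Gibbs sampler but not
  its augmentation; PG augmentation is the standard exact Gibbs scheme for
  logistic likelihoods and was implemented natively. Metropolis is the
  documented fallback for environments without the compiled sampler.
* **Filter-then-standardize.** Whether the original analysis standardized
  before or after complete-case filtering is unstated; this package filters
  first so the model scale is defined by the analysis sample.
* **Equal-tailed intervals.** Summary bounds are equal-tailed empirical
  quantiles; the reference table says only "95% credible bounds". One
  consequence is accepted deliberately: a coefficient row is flagged
  significant iff its interval excludes zero, with no attempt to reproduce
  ambiguous typography in the published table.
* **Grid versus observed points.** The band is evaluated on a regular
  factorial grid by default (the original's evaluation set is unstated);
  `apply_to_cohort()` maps observed subjects onto the classified grid by
  nearest neighbour (exact on sex, clamped at the boundary with a warning)
  for membership fractions.
* **Shrinkage check size.** The sceptical-versus-vague sd comparison is run
  on one synthetic dataset of n = 500: the inequality is analytic in the
  exact posterior, but for n ≥ 2000 the true shrinkage of well-identified
  interaction sds falls below the Monte-Carlo error of two independent
  chains (~1%), so an honest Monte-Carlo check needs a dataset where the
  prior visibly binds (measured margins ≥ 3.9% at n = 500).
* **Calibration scale.** The frequentist-calibration suite uses 200
  replicates of n = 1,500 with 2,000 retained draws and a resolution-6 grid
  — scaled down from the reference settings to fit a desk-scale test budget
  while keeping the binomial check at 2 Monte-Carlo standard errors
  meaningful.

## Known limitations

No variable selection (the covariate list must be chosen a priori, and
selection-induced multiplicity is not accounted for); no survival or
longitudinal endpoints; point estimates within selected subgroups are biased
away from zero by selection, so exports should be read as hypothesis tests,
not post-selection effect estimates; the method loses power quickly as
continuous covariates are added; membership fractions depend on the grid
span and resolution near region boundaries.

## A minimal run

```r
library(credpair)
cfg <- pipeline_config(
  out_dir = tempfile("credpair-run-"),
  generator = cohort_config(4893),
  seed = 1
)
bundle <- run_pipeline(cfg)
bundle$membership
```

Every figure written by the pipeline has a CSV twin; figures are decoration,
tables are the test surface.
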