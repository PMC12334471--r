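---
title: "Hierarchical occurrence models for fish DELT anomalies"
author: "deltscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical occurrence models for fish DELT anomalies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltscape)
```

## The problem

Visible external fish anomalies — deformities, erosions, lesions, tumors
and parasites, collectively "DELT" — are a rapid, nonlethal indicator of
fish and stream health recorded during routine community surveys. Regional
DELT datasets are assembled from many monitoring agencies whose protocols
differ (some count external parasites, some do not; some assess gill
condition, most do not), prevalence is typically low (on the order of 1–2%
of inspected fish), and candidate landscape drivers are numerous and
mutually correlated. `deltscape` implements the full analysis chain for
such data: harmonization of per-anomaly records to one binary DELT
indicator per fish, landscape-predictor preparation, hierarchical Bayesian
logistic occurrence models with sparse predictor selection, and posterior
decision summaries.

Because real multi-agency records are typically restricted, the package
also ships a synthetic-data generator that reproduces the statistical
structure those analyses assume, with known ground truth, so every stage
is testable end to end.

## Data model and harmonization

One observation is one inspected fish: a stream identifier (the spatial
unit, e.g. an NHDPlus COMID), species, collection agency, ecoregion,
calendar year and the binary DELT indicator. Records arriving as
per-anomaly flags (`present` / `absent` / `not_assessed`) are harmonized
through a user-supplied agency crosswalk: a fish is DELT-positive iff at
least one *counted* category for its agency is present. Categories an
agency did not assess, or that its crosswalk excludes, never contribute —
this is what makes an "any anomaly" indicator comparable across protocols.
Records that already carry a binary DELT flag (some agencies report only
the aggregate) pass through verbatim; the crosswalk is skipped for them.

Young-of-year exclusion is treated as an upstream data-preparation step:
if a flag column is present the reader filters on it, otherwise the data
are assumed pre-filtered, since age classification is not computable from
the fields this analysis uses.

Species-specific landscape models are only fitted for focal species with
naive prevalence at least 5% **and** sample size strictly greater than
100. Below those thresholds there is essentially no occurrence variation
to model and single-species fits are unstable.

## The three model variants

All variants are Bernoulli-logit models for the per-fish indicator
$y_{ijkrts}$ at stream $j$, agency $k$, ecoregion $r$, year $t$, species
$s$:

* **Unconditional.**
  $\Pr(y = 1) = \mathrm{logit}^{-1}(\beta_0 + \gamma_k + \phi_r + \eta_s)$
  with $\gamma_k \sim N(0, \sigma^2_{agency})$,
  $\phi_r \sim N(0, \sigma^2_{region})$,
  $\eta_s \sim N(0, \sigma^2_{species})$. No predictors; used for
  species-specific and population-average occurrence probabilities, with
  partial pooling allowing rare species to borrow strength.
* **Conditional.** Adds standardized landscape predictors:
  $\mathrm{logit}^{-1}(\beta_0 + \boldsymbol{\beta} X + \gamma_k + \phi_r
  + \eta_s)$.
* **Species-specific.** The conditional structure without the species
  random effect, fitted to a single focal species.

The year index is carried as metadata but not modeled: no year term
appears in any linear predictor.

Landscape coefficients carry a **regularized horseshoe prior**,

$$\beta_f \sim N(0, \tau^2\tilde\lambda^2_f), \qquad
\tilde\lambda^2_f = \frac{c^2\lambda^2_f}{c^2 + \tau^2\lambda^2_f},$$

with per-coefficient local scales $\lambda_f$, a global scale $\tau$, and
a slab scale $c$ bounding the magnitude of unshrunk coefficients. This
expresses the expectation that most landscape effects are (near) zero
while letting a few escape shrinkage, and is tolerant of moderate
correlation among predictors. Before fitting, predictors are additionally
screened pairwise: visiting predictors in a declared priority order
(default: column order), a predictor is dropped iff its absolute Spearman
correlation with any already-retained predictor reaches 0.90. The screen
is greedy and fully logged (every drop with its partner and $\rho$),
making the retained set deterministic and auditable; which member of a
correlated pair survives is governed by the priority order, a choice the
data themselves cannot make.

### Prior constants

Where the model family leaves constants open, the package fixes defaults
and exposes them through `model_hyper()`:

| parameter | default | rationale |
|---|---|---|
| intercept prior SD | 5 (logit scale) | weakly informative over probabilities in (0.001, 0.999) |
| half-Cauchy scale for each $\sigma$ | 2.5 | standard weakly-informative choice for logistic group SDs |
| local scale prior | half-Cauchy(1) | the horseshoe's canonical local prior |
| global scale prior | half-Cauchy$(p_0 / ((P - p_0)\sqrt n))$ | prior guess of $p_0 = 5$ nonzero effects among $P$; if $p_0 \ge P$, the guard $p_0 = P/2$ applies |
| slab | $c^2 \sim$ Inv-Gamma$(\nu/2, \nu s^2/2)$, $\nu = 4$, $s = 2$ | a Student-$t_4(0, 2)$ slab for the unshrunk coefficients |

Predictor standardization (mean 0, SD 1, sample-SD denominator) is
computed over the observation-aligned design rows by default — the rows
the likelihood actually sees, with stream values repeated per fish — with
a per-stream alternative behind the `standardize` argument. Multi-year
predictors are first collapsed to one unweighted mean of the available
annual values per stream. Missing predictor values are not imputed;
streams with any missing screened predictor are excluded from conditional
fits with a logged count.

## Inference

The posterior is explored with the package's Hamiltonian Monte Carlo
sampler (No-U-Turn criterion, slice formulation, maximum tree depth 10),
with dual-averaging step-size adaptation toward a 0.95 target acceptance
statistic and a diagonal mass matrix estimated in expanding warmup
windows. Defaults are 4 chains of 1,000 warmup plus 1,000 sampling
iterations. Random effects are non-centered by default
($\gamma_k = \sigma_{agency} z_k$, $z_k \sim N(0,1)$), which mixes far
better when groups carry weak information, as they do at 1–2% prevalence;
a centered option exists and the two agree within Monte-Carlo error (this
equivalence is a regression test). The horseshoe block is always
non-centered, and all scale parameters are sampled on the log scale with
Jacobians. Initial values are drawn from moderate-range distributions
around the priors and re-drawn (up to 10 times) on a non-finite density.

One implementation detail matters for speed: fish that share a stream
(hence a predictor row) and the same agency, ecoregion and species levels
have identical linear predictors, so before sampling the Bernoulli
likelihood is aggregated exactly into binomial success/trial counts per
distinct cell. This changes no density value — a product of identical
Bernoullis *is* the binomial kernel — but cuts the per-gradient cost by
roughly the mean cell size (about six-fold at typical survey structure).

Every source of randomness derives from the configured seed, so identical
(seed, configuration, data) reproduce bit-identical draws on one
platform.

Convergence is enforced numerically rather than visually: the verdict
passes iff every monitored parameter has split $\widehat R \le 1.01$ and
rank-normalized bulk ESS $\ge 400$, and no post-warmup trajectory
diverged (energy error above 1000). A failing verdict flags the draws; it
never deletes them.

## Posterior decision summaries

All parameters are reported as posterior means with 90% equal-tailed
credible intervals. Interval endpoints use linear interpolation of order
statistics (R's type-7 rule) — fixed and documented because at a few
thousand draws the endpoints differ between quantile rules. Effects are
classified three ways:

* `significant`: the 90% interval excludes zero;
* `pd_significant`: not significant, but the probability of direction
  exceeds 0.90 strictly — "potentially biologically significant";
* `not_significant`: everything else.

The probability of direction (pd) is the posterior probability that an
effect shares the sign of its posterior mean, computed as the larger of
the positive- and negative-sign draw fractions with draws exactly zero
counted half toward each side. That "larger of" form is the field's
standard definition; it coincides with the naive "fraction sharing the
mean's sign" whenever that fraction is the majority (always, in
practice), and it keeps pd in [0.5, 1] even for pathologically skewed
draws. The classification partitions the predictor set: significant +
pd-significant + not-significant counts always sum to the number of
fitted predictors.

Group occurrence probabilities (per species, agency or ecoregion)
summarize $\mathrm{logit}^{-1}(\beta_0 + \text{effect}_\ell)$ over draws
with the *other* random-effect blocks held at zero, their prior means —
the plug-in reading of the model equation — plus a population-average row
for $\mathrm{logit}^{-1}(\beta_0)$ alone. Marginalizing over the other
blocks' distributions instead would shift every probability upward by
Jensen's inequality; the plug-in form was chosen as the direct reading of
the printed model, and because the comparison of interest is between
levels, which the conditioning constant does not affect.

Response curves trace the posterior of
$\mathrm{logit}^{-1}(\beta_0 + \beta_f z(g))$ over a grid $g$ of one
predictor's values in original units (mapped through the stored
standardization transform), all other predictors at their study means and
random effects at zero, with mean and 90% band per grid point.

## The synthetic-data generator

`simulate_delt_dataset()` draws data from exactly the generative process
the conditional model assumes: streams receive static predictor values
from a multivariate normal (independent, block-correlated, or with a
designed near-duplicate pair at $\rho = 0.95$ to exercise the screen);
each stream belongs to one agency and one ecoregion; random effects are
drawn from their normals; each fish's DELT indicator is Bernoulli at the
inverse-logit linear predictor. Structural choices that mimic real
surveys:

* per-stream fish counts are negative-binomial (dispersion 2 by default),
  reproducing the right-skew of real survey effort; a deterministic mode
  gives exact totals for tests;
* species have log-normal relative abundances (SD 1.2 on the log scale)
  and Beta-distributed stream-inclusion probabilities, so per-species
  sample sizes and occupied-stream counts are skewed the way community
  surveys are;
* `study_mimic_config()` pins the regional scale — 57 species, 7
  agencies, 9 ecoregions, 1,196 streams, 46 predictors — and calibrates
  the intercept by Gauss–Hermite quadrature so the *marginal* prevalence
  (over random-effect and coefficient variation) hits 1.4%. Its
  random-effect SDs (agency 1.5, species 1.2, ecoregion 0.3) were chosen
  once to reproduce the qualitative pattern of multi-agency surveys:
  agency protocols dominate variation, species differ strongly,
  ecoregions differ modestly. The default per-stream mean of 8 fish
  (~29,000 fish total) is a roughly twenty-fold scale-down chosen to keep
  desk-scale runs in minutes.

What the generator deliberately does **not** emulate: spatial
autocorrelation beyond the ecoregion factor, temporal trends, seasonal
sampling imbalance, protocol-specific detection error, and realistic
landscape covariance estimated from GIS layers. Passing recovery tests
therefore demonstrate that the estimation machinery is correct *under the
model's own assumptions* — they do not validate those assumptions against
real survey data.

## Numerical and design notes

* `inverse_logit` is evaluated in a two-branch form that cannot overflow;
  the Bernoulli log likelihood uses a stable `log1p(exp(.))`.
* Constant predictor columns are rejected before standardization rather
  than silently producing NaNs; constant vectors are likewise rejected by
  the Spearman screen.
* Whether the screen should use $|\rho|$ or signed $\rho$ is genuinely
  open; the package uses $|\rho|$ (a strongly negative pair is as
  collinear as a strongly positive one) and exposes no signed option.
* Ties in `pd` at exactly the 0.90 threshold do not qualify
  (strict inequality), matching the strict "> 0.90" decision rule; a
  boundary interval endpoint exactly at zero counts as containing zero.
* Degenerate inputs: an all-zero (or all-one) outcome vector completes
  with a logged warning about the extreme intercept; an inverted study
  window, a non-PSD correlation request, unknown crosswalk agencies and
  unmatched stream identifiers all fail fast with named offenders.

## Problem sizes used in the shipped checks

The package's own validation uses scaled-down designs chosen to exercise
every code path at desk scale: oracle equivalence on $n \le 50$;
grid-oracle posterior checks at $n = 500$; sparse recovery at $n =
10{,}000$ observations, 30 predictors (5 nonzero, $|\beta| \in [0.5,
1.0]$, intercept at the 5% focal-prevalence regime, random-effect SDs
0.3) with the default 4 × (1,000 + 1,000) sampler settings; and interval
coverage over 50 replicates of $n = 1{,}000$ with 3 predictors at
reduced draw counts. The analysis scripts under `analysis/` run the
study-scale mimic (~29,000 fish) with 2 × (500–600 + 500–600) draws.

## Known limitations

* The sampler is single-threaded; chains run sequentially.
* The ecoregion random effect is the only spatial term; residual spatial
  autocorrelation within ecoregions is not modeled.
* No observation-level overdispersion term: extra-binomial variation
  loads onto the random effects.
* Group probabilities condition on other random effects at zero rather
  than marginalizing (see above); a marginalized variant would sit
  uniformly higher.
* The crosswalk is user-supplied data, not hard-coded: agencies document
  anomaly protocols too heterogeneously for a built-in table to be
  trustworthy.
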