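---
title: "Two-scale foraging habitat selection: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-scale foraging habitat selection: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habsel)
```

habsel analyses where a colonial central-place forager hunts, at two scales:
which habitat classes an individual concentrates its foraging range on
within the landscape around its colony (second-order selection), and which
of two nearby patches it strikes at within that range (third-order
selection). This vignette is the package's own account of the models, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical decisions a maintainer should know about.

## Second-order selection

### Use, availability and the selection ratio

GPS fixes at 15-minute cadence are filtered to plausible foraging locations
(see *Fix filtering* below) and counted per individual, breeding phase and
habitat class. Availability is the habitat composition of a disc of radius
3 km around the individual's colony — the species' typical foraging range —
measured on a 40-m raster of the parcel map. The raster resolution equals
the GPS location error, so a fix and a cell are commensurate; the cell
membership rule is centre-in-polygon, with ties on shared parcel edges
resolved deterministically by lowest parcel id.

The Manly selection ratio for class $k$ is

$$w_k = \frac{u_k / N}{a_k / A},$$

with $u_k$ of $N$ fixes in class $k$ against $a_k$ of $A$ available cells.
Working with *cell counts* rather than areas is deliberate: it puts use and
availability on the same integer footing, so the ratio is a ratio of two
binomial proportions and admits a score confidence interval. Hectares are
recoverable as $a_k \times 0.16$ ha.

### Koopman score intervals and weights

`koopman_ci()` inverts the score test for $\varphi = p_1/p_2$: for a
hypothesised $\varphi$ the binomial nuisance parameter is replaced by its
constrained maximum-likelihood estimate (a closed-form quadratic root), and
the interval endpoints are the two values of $\varphi$ where the score
chi-square crosses the $\chi^2_1$ quantile. Implementation details that
matter:

* The statistic is computed in its two-component form
  $\sum_j (x_j - n_j\tilde p_j)^2 / (n_j\tilde p_j(1-\tilde p_j))$. The
  popular single-term reduction is algebraically equivalent in the interior
  but degenerates numerically when $u_k = N$ (the constrained estimate hits
  1); the two-term form with consistent clipping at $10^{-12}$ handles that
  limit and still yields a finite upper bound.
* Roots are found by `uniroot` on $\log\varphi$ (tolerance $10^{-10}$) with
  a geometrically expanded bracket; $u_k = 0$ fixes the lower bound at 0 and
  searches only upward. A bound that cannot be bracketed within
  $e^{\pm 60}$ of the estimate is reported as infinite.
* Ratios are computed only for classes with at least `min_use = 5` used
  locations, the standard rule of thumb for credible per-animal ratios,
  applied per individual × phase × class (`min_use = 0` restores all rows;
  the flag, not silent deletion, records the rule).

Each ratio is weighted by the reciprocal of its CI length, so imprecise
ratios count less in the population model. When a bound is infinite the
weight uses a capped length of 10 × the point estimate, and the capping is
messaged rather than hidden.

### The population model

`fit_ratio_glmm()` fits, separately per phase,

$$\log E[w] = \beta_{\text{habitat}} + b_{\text{individual}} + b_{\text{colony}},
\qquad w \sim \text{Gamma},$$

with the CI-length weights as prior weights (they divide each observation's
gamma dispersion) and Laplace-approximated maximum likelihood (lme4,
bobyqa with `rhoend = 1e-10` for reproducible optima). Choices made where
the design was genuinely open:

* **Crossed, not nested, random intercepts.** The grouping statement
  "individual and colony" is read as two crossed intercepts; `random =
  "nested"` is available. With only two colonies the colony variance
  routinely collapses towards zero — this is reported, never suppressed.
* **Canonical row ordering.** Observations are sorted internally before
  fitting, so the estimate depends on the data as a set and permuting input
  rows reproduces estimates exactly.
* **Zero-variance diagnostic.** `fix_zero_variance = TRUE` pins both
  random-intercept variances at zero inside the mixed-model machinery
  (penalized IRLS at $\theta = 0$). At that boundary the Laplace objective
  coincides with the weighted gamma GLM, which is the package's oracle
  check that the mixed route is wired correctly.

The habitat factor is tested with a Wald chi-square
($\chi^2 = \hat\beta' V^{-1} \hat\beta$ over the 7 contrasts of the 8-level
factor). Variance explained by habitat alone is Nakagawa's marginal
$R^2 = \sigma_f^2 / (\sigma_f^2 + \sigma_{ind}^2 + \sigma_{col}^2 +
\sigma_\varepsilon^2)$, where the observation-level variance of the gamma
log-link model uses the trigamma method, $\psi_1(1/\hat\phi)$, by default;
`obs_var = "lognormal"` switches to $\log(1+\hat\phi)$.

### Fix filtering

`filter_fixes()` applies, in order of precedence: the night window
(20:00–06:00 local, boundary instants removed — roosting birds, not
foraging ones, are recorded then); a colony exclusion buffer (default 50 m,
per-colony overrides such as 80 m where observation shows no foraging
closer) padded by the 40-m GPS error; and the 3-km foraging radius.
Individuals are kept only with an active nest, ≥ 100 retained fixes and
≥ 10 distinct tracking days. "Days" is read as distinct local calendar
dates with at least one retained fix (the stricter of the two plausible
readings; a tracking *span* reading would retain more birds). Filtering is
idempotent and monotone in the buffer sizes, and both properties are
tested.

## Third-order selection

Each observed foraging strike is paired with a control point 500 m away at
a uniformly random bearing — far enough to fall in a different ~10-ha field,
near enough to be certainly reachable. With one control per case the
conditional likelihood depends only on within-pair covariate differences
$d_i = x_{f,i} - x_{c,i}$:

$$\ell(\beta) = \sum_i \left[\beta'd_i - \log(1 + e^{\beta'd_i})\right],
\qquad \ell_{\text{null}} = n\log\tfrac12 .$$

`fit_pair_clogit()` maximises this by Newton–Raphson with step-halving
(stop at $|\Delta\ell| < 10^{-10}$, max 50 iterations). Numerical edge
cases:

* **Tied pairs** contribute $\log\frac12$ each and cannot move
  $\hat\beta$; a fit with no informative pairs returns $\beta = 0$ with a
  `zero_information` flag and pseudo-R² 0.
* **Complete separation** (all informative differences favouring one role)
  sends $\hat\beta$ to infinity along a likelihood plateau. It is detected
  either by a coefficient exceeding 15 on the log-odds scale or by every
  informative pair reaching fitted probability > 0.999, and reported as a
  flag — never returned silently as a finite estimate.
* **Structurally empty factor levels** (a level appearing in no within-pair
  difference) are dropped from the design with their names recorded in
  `dropped_levels`, since their coefficients are not estimable.

The three models — height, structure, crop — are always fitted separately:
height is not independent of structure or crop, and a combined model would
answer none of the three questions cleanly. For the crop model the default
uses every pair in which both members carry one of the five crop labels;
`crop_subset = "vegetated"` restricts to pairs vegetated on both sides, the
narrower reading of "selection among vegetated crops". Reference levels
default to vegetated (structure) and alfalfa (crop); `pairwise_contrasts()`
reports every level pair as "A vs. B = coefficient of B with A as
reference", which is exactly reproducible by refitting with the reference
changed (tested to $10^{-8}$).

## The synthetic study

`sim_config()` states a world; the generator never adapts it to make tests
pass. Its defaults are, in order of provenance:

* **Stated by the study design**: 10-ha fields; crop cover alfalfa 18%,
  winter cereals 33%, other non-irrigated 3%, maize 8%, other irrigated
  20%; 15-min GPS cadence; 3-km foraging radius; 500-m controls; 411 pairs;
  9 birds split 2/7 across two colonies; season 31 May – 25 July spanning
  the three phases (late incubation, early and late nestling rearing).
* **Chosen once as realistic, documented here**: the residual 18% of cover
  split urbanized 10% / water 3% / semi-natural 5%, typical of an
  intensively cultivated plain with scattered farmsteads; the phenology
  transition table (alfalfa alternates vegetated/harvested all season under
  repeated cutting; winter cereals and other non-irrigated crops go from
  90% vegetated in phase 1 to fully harvested-or-ploughed in phase 3; maize
  and other irrigated crops stay vegetated); truncated-normal vegetation
  heights per crop × state × phase, invented but constrained so stubble is
  always shorter than the standing crop and phase-3 maize exceeds 2 m; and
  per-phase preference weights that encode the seasonal shift the analyses
  are designed to detect (alfalfa and freshly sown maize early, cereals
  after harvest, urbanized areas and water always avoided).
* **True parameters under test**: the conditional height slope
  $\beta_h = -0.06$ per cm, and the preference weights above.

Pair labelling uses the exact generative dual of the conditional logistic
likelihood: given the two candidate locations, the first is labelled
"forage" with probability $e^{\beta_h h_1}/(e^{\beta_h h_1} +
e^{\beta_h h_2})$. This makes the fitted slope consistent for $\beta_h$ *by
construction*, which is the point: a green recovery test certifies the
estimator and the plumbing, not the realism of kestrel behaviour. Pairs
draw their dates across the first two phases, matching a May–June
observation season, so all three structure states occur.

What the generator deliberately does **not** emulate: flight paths and
serial autocorrelation of fixes (daytime cell draws are i.i.d. by default,
matching the independence the count-based estimators assume; a first-order
distance-kernel option `movement = "markov"` exists for robustness
experiments only), weather, prey fields, observer bias in pair placement,
and between-individual preference heterogeneity (all birds share one
preference vector, which inflates the marginal R² of the population model
relative to field data). A green end-to-end test therefore establishes
correctness of the estimators under their own assumptions — not
transferability to data violating them.

All randomness derives from one integer seed (streams for landscape,
per-bird tracks and pairs are fixed offsets of it), and `simulate_study()`
is bit-for-bit reproducible from `(config, seed)`.

## Known limitations

* The Koopman interval treats availability as a binomial count sample; with
  availability fixed and known, the interval is conservative (empirical
  coverage for the use proportion sits at or slightly above nominal — the
  coverage test asserts the 0.93–0.97 band).
* Wald tests and SEs are asymptotic; at few informative pairs or few
  individuals they are only approximate, which the null-calibration tests
  bound but do not remove.
* Only 1:1 matched strata are supported (the general Breslow/exact
  likelihood for larger strata is out of scope), and the pipeline has no
  home-range estimator — availability is the colony disc by design.
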