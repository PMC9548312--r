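# habsel

Foraging habitat selection for colonial central-place foragers, at two of
Johnson's orders of selection. The package was built around the study design
used for lesser kestrels (*Falco naumanni*) breeding in intensively
cultivated lowlands, where habitat quality turns over within weeks as crops
are cut, harvested and ploughed — but every component is generic to any
use-vs-availability + matched-pairs design.

## What it computes

**Second-order selection (GPS tracking).** For each tracked individual,
breeding phase and habitat class, the Manly selection ratio

    w = (u / N) / (a / A)

compares the used proportion (`u` of `N` retained GPS fixes) with the
available proportion (`a` of `A` 40-m raster cells inside a 3-km colony
buffer). `w > 1` is preference, `w < 1` avoidance. Each ratio carries a
Koopman score confidence interval — the score test for a ratio of two
binomial proportions, inverted with constrained maximum-likelihood nuisance
estimates — and enters a population-level model weighted by the reciprocal
of its CI length:

    ratio ~ habitat + (1 | individual) + (1 | colony),  Gamma, log link

fitted by Laplace approximation (lme4), with a Wald chi-square test of the
8-level habitat factor and Nakagawa's marginal R² (trigamma method) for the
variance explained by habitat alone.

**Third-order selection (paired field observations).** Each observed
foraging location is matched to a control point 500 m away at a random
bearing. With 1:1 matching the conditional logistic likelihood reduces to a
no-intercept logistic regression on within-pair covariate differences:

    L(beta) = prod_i exp(beta' x_f,i) / (exp(beta' x_f,i) + exp(beta' x_c,i))

Three separate models — vegetation height (cm), vegetation structure
(vegetated / harvested / ploughed) and crop type (5 levels) — are fitted by
Newton–Raphson, with joint Wald tests, all pairwise level contrasts, and
McFadden's pseudo-R² = 1 − logL(model)/logL(null), where the null assigns
each pair a coin flip.

**Synthetic study generator.** `simulate_study()` builds a ~10-ha parcel
mosaic with per-phase crop phenology, preference-driven GPS fixes at 15-min
cadence (plus deliberate night roost fixes for the filters to remove), and
matched pairs whose forage/control labelling follows the exact generative
dual of the conditional logistic likelihood — so parameter recovery is
testable end to end with no field data.

## Worked example

```r
library(habsel)
cfg <- sim_config(seed = 7, n_days = 21, n_individuals = 4, n_pairs = 300)
sim <- simulate_study(cfg)
res <- run_pipeline(sim)

head(as.data.frame(res$ratios)[, c("individual","class","u","N","ratio","lo","hi","weight")], 5)
#>   individual   class   u   N ratio   lo   hi weight
#> 1    bird_03 alfalfa 224 874  1.89 1.68 2.13   2.22
#> 2    bird_04 alfalfa 216 877  1.82 1.61 2.05   2.26
#> 3    bird_01 alfalfa 241 877  1.86 1.65 2.07   2.38
#> 4    bird_02 alfalfa 258 876  1.99 1.78 2.21   2.32
#> 5    bird_03   maize 136 874  1.59 1.35 1.87   1.95
```

Each row says: this bird placed `u` of its `N` late-incubation fixes in the
class, against availability `a/A`; alfalfa is used almost twice as often as
expected by chance (ratio ≈ 1.9, CI excluding 1), as the generator's
late-incubation preference weights dictate. At the population level:

```r
g <- res$glmm$late_incubation
#> Wald chi2 = 4527.53 (df 7), marginal R2 = 0.90
```

habitat class explains most of the latent variance in ratios (simulated
birds share one preference vector, so R² runs higher than a field study
would show). The third-order models:

```r
res$clogit$height
#> Matched-pair conditional logistic model (height)
#>   pairs: 300 (informative: 299)
#>               estimate     se     z
#> veg_height_cm  -0.0499 0.0058 -8.64
#>   logLik: -123.545 (null -207.944), McFadden pseudo-R2: 0.406

pairwise_contrasts(res$clogit$structure)
#>                  contrast estimate    se    z        p
#> 1 vegetated vs. harvested     2.11 0.355 5.94 2.89e-09
#> 2  vegetated vs. ploughed     3.22 0.706 4.57 4.98e-06
#> 3  harvested vs. ploughed     1.12 0.654 1.71 8.73e-02
```

The fitted height slope (−0.050 ± 0.006 per cm) recovers the generating
value −0.06 within two standard errors: every centimetre of vegetation
roughly halves the odds of foraging per 14 cm. The structure contrasts read
"A vs. B = log-odds of B relative to reference A": harvested and ploughed
fields are both strongly preferred over standing vegetation.

`run_pipeline(sim, out_dir = "out")` additionally writes
`selection_ratios.csv`, `glmm_tests.csv`, `clogit_models.csv` and a
`run_log.json` carrying drop tallies and the config hash.

## Acceptance script

`scripts/acceptance.R` regenerates a full synthetic study from a seed and
runs the entire chain — landscape, tracks, fix filtering and QC, selection
ratios with Koopman intervals, the three per-phase weighted gamma GLMMs and
the three matched-pair conditional logistic models — then writes its JSON
report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Stage summaries (Wald chi-squares, marginal R², log-likelihoods, pseudo-R²)
are printed to stderr as it runs.
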