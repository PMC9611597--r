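# starmnl

Bayesian multinomial structured geo-additive regression for clustered
categorical survey data, with k-modes classification and spatial
summaries.

## What this package is for

Surveys such as the Demographic and Health Surveys interview women inside
small geographic clusters (primary sampling units, PSUs) nested in
first-level administrative regions.  A recurring question is whether a
categorical outcome — here, a respondent's *empowerment category* derived
from ten attitude and decision-making items — varies geographically beyond
what individual characteristics (age, education, household income,
urban/rural residence) explain.  `starmnl` implements the full analysis
chain for that question:

1. **Classification.**  k-modes clustering of the ten nominal items
   (simple matching distance, item-wise plurality modes), primed with five
   conceptually meaningful initial modes ("more empowered", "less
   empowered", "modal empowered", "autonomous", "other").
2. **Spatial summary.**  PSU-level proportions of the three dominant
   categories, a tri-colour blend (blue/red/green for categories 1/2/3)
   for map rendering, and Moran's I for spatial autocorrelation.
3. **Model.**  A fully Bayesian multinomial-logit structured additive
   regression.  With category 3 as reference (η<sub>ij3</sub> = 0), for
   k = 1, 2:

   η<sub>ijk</sub> = **x**<sub>ij</sub>′ **β**<sub>k</sub> + f<sub>k</sub>(a<sub>ij</sub>) + b<sub>u(ij),k</sub> + s<sub>jk</sub>

   with flat priors on the eight fixed effects **β**<sub>k</sub>, a
   degree-3 P-spline f<sub>k</sub> on age (M = 23 basis functions,
   second-order random-walk prior), iid Gaussian PSU effects b, an
   intrinsic Markov-random-field prior on region effects s (conditional
   mean = neighbour average, conditional variance τ²<sub>s</sub>/N<sub>j</sub>),
   and IG(0.001, 0.001) hyperpriors on all three variances.  Estimation is
   Gibbs sampling with Polya-Gamma augmentation (implemented in C++).
   Dropping the MRF term gives the *null* model; models are compared by
   DIC and by the residual Moran's I of the PSU effects.
4. **Diagnostics.**  Geweke z-scores and Gelman–Rubin potential scale
   reduction factors (univariate and multivariate).
5. **Synthetic data.**  A generator that emulates the two-stage survey
   design — 15–100 respondents per PSU, several PSUs per region,
   coordinates jittered by up to 2 km (urban) / 5 km (rural), covariate
   composition optionally confounded with region — from a known ground
   truth, so clustering recovery, parameter recovery and full-vs-null
   comparisons are testable without restricted microdata.

## Worked example

```r
library(starmnl)

graph <- build_region_lattice(4, 4)                 # 16 regions, rook adjacency
sim   <- simulate_survey(graph, ground_truth(),
                         psus_per_region = 4,
                         respondents_per_psu = c(15, 25), seed = 1)
km    <- kmodes(sim$data)                           # primed k-modes
km
#> k-modes clustering: 5 modes, 1291 observations
#> cluster sizes: 702, 223, 364, 1, 1
#> matching cost: 652 (converged in 3 iterations)

dat <- sim$data
dat$category <- km$cluster
fit_full <- star_mnl(category ~ urban + educ + income + s(age) + re(psu) + mrf(region),
                     data = dat, graph = graph,
                     iterations = 4000, burnin = 1000, thin = 5, seed = 2)
fit_null <- star_mnl(category ~ urban + educ + income + s(age) + re(psu),
                     data = dat,
                     iterations = 4000, burnin = 1000, thin = 5, seed = 3)
fit_full
#> Multinomial-logit structured additive regression (full model)
#>   1289 respondents in categories 1-3; reference category k = 3
#>   1 chain(s) x 4000 iterations (burn-in 1000, thinning 5): 600 retained draws each
#>   terms: fixed effects + P-spline age smooth + iid PSU effects + MRF region effects
#>   DIC = 2369.1 (Dbar = 2317.7, pD = 51.4)

c(full = fit_full$dic[["DIC"]], null = fit_null$dic[["DIC"]])
#>     full     null
#> 2369.105 2397.884

rbind(full = morans_psu_effects(fit_full, dat, graph)$morans_i,
      null = morans_psu_effects(fit_null, dat, graph)$morans_i)
#>             [,1]        [,2]
#> full -0.09060462 -0.05045783
#> null  0.53458186  0.20030674
```

The spatial model fits better (lower DIC) and absorbs the spatial signal:
the region-aggregated Moran's I of the residual PSU effects drops from
0.53/0.20 (null) to −0.09/−0.05 (full) for the two non-reference
categories — the synthetic analogue of the reduction seen when a
structured region effect is added to a real geo-additive analysis.
`summary(fit_full)` reports posterior medians and 95% credible intervals
of the fixed effects as relative odds ratios against the reference
category; `age_effect()`, `region_effects()` and `psu_effects()` extract
the smooth and the random-effect summaries; `diagnose()` reports Geweke
and Gelman–Rubin diagnostics.

`run_pipeline(config, out)` executes the whole chain (simulate → cluster
→ map → fit full/null → compare → diagnose) and persists every artifact
(survey.csv, labels.csv, map.csv, dic_comparison.csv,
morans_comparison.csv, diagnostics.csv, run log) reproducibly from one
master seed.

## Package layout

- `R/region-graph.R` — adjacency graphs, lattice builder, intrinsic GMRF
  sampling, plain-text graph files
- `R/kmodes.R` — items, templates, matching distance, batch k-modes
- `R/synthetic.R` — ground truth, response emission, survey simulation, IO
- `R/design.R` — covariate coding, B-spline basis, RW2 penalty,
  multinomial probabilities, log-likelihood
- `R/star-mnl.R`, `src/star_mcmc.cpp` — the model, Polya-Gamma Gibbs
  sampler, DIC, posterior summaries, S3 methods
- `R/spatial-summary.R` — PSU proportions, colour blending, Moran's I
- `R/diagnostics.R` — Geweke, Gelman–Rubin, spectral variance, ESS
- `R/pipeline.R` — end-to-end orchestration
- `vignettes/geoadditive-empowerment.Rmd` — methods vignette
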