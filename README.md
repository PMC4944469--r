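# lactscale

Allometric scaling of maternal metabolizable energy intake (MEI) during
lactation.

Lactation is the most energy-expensive episode of a mammalian mother's
life: after parturition her daily metabolizable energy intake climbs from
an initial rate to a peak several weeks later. `lactscale` implements a
comparative analysis of how the characteristics of that intake-elevation
pattern scale with maternal body mass across species, for researchers in
comparative energetics and phylogenetic comparative methods. It covers:

- **Pattern characteristics** — from each intake time series (MJ/day vs
  day postpartum, day 0 excluded): initial rate, peak rate and time to
  peak, average rate, amplitude (peak − initial), and the cumulative
  elevation to peak (rectangle-rule sum of the excess over the initial
  rate, in MJ).
- **Growth-curve decomposition** — a generalized Von Bertalanffy model
  for the cumulative elevation, `C(t) = A (1 − e^{−kt})^c`, fitted per
  pattern by bounded Levenberg–Marquardt least squares. For `c > 1` the
  extra-intake rate `C'(t)` peaks at `t* = ln(c)/k`, with amplitude
  `A k (1 − 1/c)^{c−1}` and cumulative elevation to peak
  `A (1 − 1/c)^c`, tied together by the dimensionless shape statistic
  `(1 − 1/c)/ln(c)`: cumulative-to-peak = amplitude × time-to-peak ×
  shape. Shape 0.5 means a linear rise (triangular area), above 0.5 a
  decelerating rise. Fits are screened by nRMSE and a Tukey-fence rule
  on the model-vs-raw time-to-peak discrepancy.
- **Curvilinear allometry** — for each characteristic `y`,
  `log10 y = intercept + b1·log10 M + b2·(log10 M)² + diet_coef·d`
  (mass `M` in kg, `d` the diet ME density in MJ/kg dry matter), so the
  local scaling exponent is mass-dependent: `b = b1 + b2·log10 M`.
  Species and breed-within-species enter as random effects; the species
  effect is phylogenetically structured through the Brownian covariance
  of an ultrametric tree with Pagel's λ sampled as a model parameter.
  Fitting is by a Gibbs sampler (animal model; RcppArmadillo core) with
  a non-phylogenetic REML route (lme4) alongside, reporting posterior
  means, 95 % credible intervals, pMCMC, variance components, λ and the
  marginal (fixed-effect) r².
- **Synthetic data** — a generator producing datasets with the assumed
  statistical structure (pure-birth tree, log-uniform masses 0.01–600 kg,
  heavy-tailed replication, daily vs weekly sampling, sigmoid
  trajectories, phylogenetic species effects), so the whole pipeline is
  testable end to end.

## Worked example

```r
library(lactscale)

sim <- simulate_dataset(sim_config(), seed = 7)   # 52 patterns, 24 species
tab <- characteristics_table(sim$patterns)
fit <- fit_phylo_mcmc(build_design(tab, "peak_rate"), sim$tree, seed = 3)
fit
#> <scaling_fit> phylogenetic animal model (Gibbs MCMC)
#>           estimate    lo95   hi95     p
#> intercept  -0.0691 -0.1928 0.0570 0.273
#> b1          0.6737  0.6494 0.6967 0.001
#> b2          0.0333  0.0096 0.0570 0.010
#> diet_coef   0.0206  0.0104 0.0306 0.001
#> variance components: phylo=0.00397, breed=0.00132, resid=0.00318
#> lambda = 0.546
#> marginal r2 = 0.988

local_exponent(0.67, 0.050, c(0.05, 500))
#> [1] 0.6049485 0.8049485
```

The fit recovers the generating law (b1 = 0.667, b2 = 0.050,
diet_coef = 0.024 on this synthetic dataset): intake rates scale with a
mass-dependent exponent `b1 + b2·log10 M`, rising from about 0.60 for a
50-g mother to about 0.80 for a 500-kg one, with the diet's energy
density shifting the normalization constant. `run_pipeline()` chains all
stages (characteristics → Von Bertalanffy fits and exclusions → scaling
regressions with and without phylogeny → optional species-averaged,
onset-mass, shape-covariate and ratio variants) and writes TSV/JSON
reports.

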