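---
title: "Scaling of maternal energy intake during lactation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling of maternal energy intake during lactation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lactscale` analyses how the elevation of maternal metabolizable energy
intake (MEI, MJ/day) during lactation scales with body mass across
mammals. This vignette is the package's own account of the models it
implements, the choices behind them, and what the accompanying tests do
and do not establish.

## The intake-elevation pattern and its characteristics

A pattern is one lactation time series of MEI with its covariates: diet
metabolizable-energy density (MJ/kg dry matter), maternal body mass at
the time of peak intake and at lactation onset (kg), and species/breed
labels. Day 0 — the day of parturition — is excluded; a pattern needs at
least three analysable measurements because the growth model below has
three parameters.

Six raw characteristics are extracted (`pattern_characteristics()`):

| quantity | units | definition |
|---|---|---|
| initial rate | MJ/day | MEI at the first measurement after day 0 |
| peak rate, time to peak | MJ/day, days | maximum of the analysable series and its day; ties broken at the earliest day |
| average rate | MJ/day | mean of all measurements from the initial through the peak, inclusive |
| amplitude | MJ/day | peak − initial |
| cumulative elevation to peak | MJ | rectangle-rule sum of (MEI − initial) × grid spacing up to the peak |

Choices worth flagging:

- **Rectangle rule, not trapezoid.** The cumulative elevation is a sum
  of differences times the sampling interval (1 day for daily data, 7
  for weekly). On daily data this is what "summing the daily excess"
  means; switching to a trapezoid rule would change values by less than
  the measurement noise but break the simple sum interpretation.
- **Inclusive endpoints for the average rate.** Whether the mean "between
  the initial and the peak" includes the endpoints is ambiguous;
  both endpoints are included here, and the tests pin that convention.
- **Peak detection.** The default is the global maximum of the
  analysable points — deterministic and reproducible. An opt-in robust
  mode takes the maximum of a centred 3-point running-median smooth so a
  single-day spike does not define the peak. A peak on the last
  measurement is flagged (`peak_at_end`) as possibly not reached.

## Growth-curve decomposition

The cumulative elevation is modelled with a generalized Von Bertalanffy
curve,

$$C(t) = A\,(1 - e^{-kt})^c,$$

with asymptote $A$ (MJ), rate $k$ (1/day) and dimensionless exponent
$c$. Its derivative $C'(t) = A c k\, e^{-kt} (1-e^{-kt})^{c-1}$ is the
extra-intake rate. Setting $C''(t^*) = 0$ gives $e^{-kt^*} = 1/c$, so
for $c > 1$:

- time to peak $t^* = \ln(c)/k$ (natural log — with any other base the
  identities below fail),
- amplitude $C'(t^*) = A k (1 - 1/c)^{c-1}$,
- cumulative elevation to peak $C(t^*) = A (1 - 1/c)^c$,

which combine into the exact identity

$$C(t^*) = \underbrace{(1-1/c)/\ln(c)}_{\text{shape}} \times
  \text{amplitude} \times t^*.$$

The shape statistic is the area of the rise relative to the enclosing
rectangle: 0.5 for a perfectly linear rise (right-triangle area), above
0.5 for a decelerating (concave-down) elevation, below 0.5 for an
accelerating one. It decreases strictly from 1 (as $c \to 1^+$) toward 0
(as $c \to \infty$). For $c \le 1$ the rate has no interior maximum and
the decomposition is undefined; `derived_characteristics()` errors
rather than extrapolating.

**Fitting.** `fit_vb()` rebuilds the cumulative series from the pattern
(re-zeroed at the initial measurement) and fits $(A, k, c)$ by
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with box
constraints $A \in (0, 10\,\max C]$, $k \in (0, 10]$, $c \in (1, 100]$
and starting values $A_0 = 1.05 \max C$, $c_0 = 2$,
$k_0 = \ln(c_0)/t^{raw}_{peak}$ — near the basin of attraction for any
sigmoid series. Goodness of fit is the RMSE divided by the observed
range (nRMSE), reported for the cumulative and for the extra-rate series
(the latter is always the harder target). Fits whose model-vs-raw
time-to-peak relative difference falls outside the Tukey fences
(Q1 − 1.5 IQR, Q3 + 1.5 IQR) of the cohort are flagged abnormal — a
deterministic, documented replacement for visual screening; with fewer
than four converged fits the screen is skipped with a warning, and a
zero-IQR cohort flags nothing.

## Curvilinear allometry with phylogeny

Each characteristic $y$ is modelled on the log10 scale with mass in kg:

$$\log_{10} y = \beta_0 + b_1 x + b_2 x^2 + \beta_d\, d
  + u_{species} + u_{breed} + \varepsilon, \qquad x = \log_{10} M,$$

equivalently $y = a\,M^{\,b_1 + b_2 \log_{10} M}$ with
$a = 10^{\beta_0 + \beta_d d}$. The local scaling exponent at mass $M$
is therefore $b_1 + b_2 \log_{10} M$ (`local_exponent()`); kg and log10
are load-bearing, since the exponent arithmetic at 0.05 kg and 500 kg
only works in those units.

Two routes are provided behind the same interface:

- **REML (`fit_lmm()`)**: lme4 with species and breed-within-species
  intercepts; Wald 95 % intervals; singular fits report a zero component
  with a warning. No phylogeny.
- **MCMC animal model (`fit_phylo_mcmc()`)**: the species effect has
  covariance $\sigma^2_{phylo}\,V_\lambda$ with
  $V_\lambda = \lambda V + (1-\lambda) I$, where $V$ is the Brownian
  covariance of the unit-height ultrametric tree (shared root-to-MRCA
  branch length) and $\lambda$ is Pagel's signal parameter. Repeated
  measures per species enter through an incidence matrix without any
  weighting, so heavily studied species contribute all their patterns.
  A Gibbs sampler (RcppArmadillo) updates $(\beta, u)$ jointly from
  their multivariate-normal conditional and each variance from its
  inverse-gamma conditional; $\lambda$ gets a reflected random-walk
  Metropolis step that exploits the fact that $V_\lambda$ shares the
  eigenvectors of $V$, so each update only reshifts eigenvalues.

**Why λ is sampled rather than derived from variance components.** A
common convention reports λ as the heritability-style ratio
$\sigma^2_{phylo}/(\sigma^2_{phylo}+\sigma^2_{breed}+\sigma^2_{resid})$.
With this model structure that ratio is insensitive to the actual
phylogenetic structure of the species effects: $V$ has unit diagonal, so
the phylogenetic term can absorb independent species-level variance
wholesale and the ratio measures only the species-level variance share.
Simulation under the package's own generator confirms it does not order
with the generating signal. Sampling λ as a parameter (uniform prior)
restores a consistent estimator; the heritability ratio is still
reported as `phylo_heritability` for comparison with that convention.

**Priors and summaries.** Flat priors on fixed effects; inverse-gamma
(0.001, 0.001) on each variance — weakly informative at these data
scales and configurable (`priors=`); variances can also be pinned, which
turns the sampler into a GLS draw (used by the validation tests).
Summaries: posterior means, equal-tailed 95 % credible intervals, and
pMCMC $= 2 \min(\Pr(>0), \Pr(<0))$ floored at $2/n_{kept}$ so p-values
are never exactly zero. Marginal r² is the Nakagawa–Schielzeth fixed-
effect share $\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) +
\sum \sigma^2)$. A split-half $\widehat R > 1.1$ on any coefficient
triggers a warning.

**Chain lengths.** Defaults are 60,000 iterations, 10,000 burn-in,
thinning 25 — 2,000 retained draws, a few seconds per fit, and stable
summaries at this problem size (about 50 patterns, 24 species).
Production-scale chains (e.g. 1,000,000/15,000/100) are a single
argument away and change nothing but Monte-Carlo error.

**Trees.** Newick in/out via ape with validation; species names are
matched after case folding and underscore/space normalization, and
unmatched species are excluded from phylogenetic analyses with a
warning. Trees are scaled to unit height before use so
$\sigma^2_{phylo}$ is comparable across trees. Pruning keeps the
dropped basal path as a root edge, so the covariance of a pruned tree is
exactly the corresponding submatrix of the full covariance.
Multifurcations are accepted as-is. Whether to rescale after pruning is
genuinely open in comparative practice; unit-height scaling is this
package's documented choice, not a claim about anyone else's.

**Variants.** `species_average_analysis()` collapses to one point per
species (dropping the breed term) — the commonly practiced analysis that
discards within-species information; `build_design(..., mass_column =
"onset")` swaps in mass at lactation onset; `ratio_scaling()` fits the
log ratio of two characteristics and back-transforms the intercept at
the mean diet density into a fold change; `shape_covariate_run()` adds
the fitted shape statistic to the cumulative-elevation regression. The
pipeline (`run_pipeline()`) chains everything with per-stage error
tagging, exclusion logging and deterministic seeding.

## The synthetic-data generator

`simulate_dataset()` produces datasets with the statistical structure
the analysis assumes — it defines the study conditions for every test:

- **Tree**: pure-birth (Yule), rescaled to unit height — the simplest
  process giving ultrametric trees with non-trivial covariance.
- **Species**: 24 by default, masses log-uniform over 0.01–600 kg
  (shrew-to-cattle; even leverage in log-mass is where the curvilinear
  term gets its power); diet densities uniform on 8–14 MJ/kg DM.
- **Replication**: 52 patterns; every species contributes one and five
  randomly chosen species absorb the surplus, emulating the heavy-tailed
  replication of compiled literature data; replicated species get 2–3
  breed labels.
- **Scaling laws**: the primary law generates the log10 peak rate with
  coefficients defaulting to phylogeny-controlled estimates typical of
  such data (intercept −0.233, b1 0.667, b2 0.050, diet 0.024); the
  initial rate follows the same law shifted down by log10(1.9) — a
  mass-independent 1.9-fold intake increase to the peak — with its own
  residual, and the amplitude is their difference, so amplitude scaling
  stays parallel to the rates and the peak/initial ratio carries no mass
  effect by construction. Time to peak has its own law (1.266, 0.078,
  0.036, −0.001 on log10 days).
- **Random effects**: one phylogenetic species effect (SD 0.08 log10
  units, Pagel λ 0.65 by default, marginal variance independent of λ by
  construction), breed effects (SD 0.035), per-characteristic residuals
  (SD 0.045). These place the rate regressions near r² ≈ 0.99 with a
  clearly weaker mass signal for time to peak.
- **Trajectories**: the Von Bertalanffy exponent is drawn as
  $c = 1 + \mathrm{lognormal}(\log 1.5, 0.45)$ (median c 2.5, mean shape
  ≈ 0.66, always an interior peak), $k$ and $A$ are solved so the drawn
  characteristics are reproduced exactly before noise, and the emitted
  MEI series is initial + $C'(t)$ on a daily grid (species under 10 kg)
  or as weekly interval means tagged at interval midpoints (10 kg and
  above), observed 1.6× past the peak, times multiplicative lognormal
  noise (CV 5 % — the compiled studies report no per-pattern measurement
  error, so this is a simulation knob, not an estimate).

What the generator does **not** emulate: digitization error from
published figures, body-mass change over lactation beyond a small
onset/peak offset, diet changes within a lactation, missing days,
non-mammalian-shaped trees, or trait evolution beyond Brownian-with-λ.
Passing tests therefore show that the estimators recover the assumed
structure at realistic sizes and noise — not that real compiled data
satisfy those assumptions.

## Numerical and testing notes

- Recovery tests run the regression on the generator's recorded
  generating characteristics; extraction from noisy discrete series is
  exercised separately, because grid maxima are biased slightly below
  (discretization) or above (noise maxima) the continuous peak.
- Tolerances: exact algebraic identities are tested to 1e-10; quadrature
  cross-checks to 1e-8; Monte-Carlo comparisons at 2–5 % of the quantity;
  the linear-rise shape lands within 0.05 of 0.5 when the pattern is
  observed over its full course.
- Problem sizes in the suite — 24 species / 52 patterns, 20 replicates
  for interval coverage, 60,000-iteration chains — were chosen to match
  the data scale the analysis targets while keeping a full run of the
  suite in minutes.
- All randomness flows from explicit seeds; a pipeline run with the same
  config and seed is byte-identical.

## Known limitations

- The Metropolis step for λ is tuned with a fixed proposal SD (0.12);
  acceptance is reported but not adapted.
- pMCMC is a sign-based tail probability, not a posterior model
  comparison; with 2,000 retained draws its floor is 0.001.
- The abnormal-fit screen needs a cohort; single-pattern analyses skip
  it.
- With a single breed level per species the breed variance is
  unidentifiable and the REML route drops it (the MCMC route's prior
  keeps it proper but uninformative).
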