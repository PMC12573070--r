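---
title: "Modelling spatio-temporal trends in endophyte prevalence from herbarium specimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatio-temporal trends in endophyte prevalence from herbarium specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endotrend)
library(dplyr)
```

## The scientific problem

*Epichloë* fungal endophytes are seed-transmitted symbionts of cool-season
grasses. Because the fungus is preserved inside the seeds that grass
specimens carry on herbarium sheets, the symbiont's presence or absence can
be scored microscopically in specimens collected over the last two
centuries. Each scored specimen is one Bernoulli observation of symbiont
prevalence at a known place and time, and a collection of them supports
inference about how prevalence has moved across a host species' range as
climate changed.

Herbarium data are, however, neither a designed survey nor spatially
uniform: collection effort clusters around particular institutions and
decades, the same prolific collectors contribute many sheets, and the
microscopists ("scorers") who call endophyte status differ in their
propensity to call a positive. **endotrend** implements an analysis built
around these realities: a joint-species spatially-varying-coefficient (SVC)
logistic model with observer random effects, fitted as a latent Gaussian
model, plus the downstream climate attribution and validation machinery, and
a synthetic-data generator so that every stage can be exercised and tested
without any external downloads.

## The model

For host species $h$ and specimen $i$ with binary endophyte status
$P_{h,i}$,

$$
P_{h,i} \sim \mathrm{Bernoulli}(\hat P_{h,i}), \qquad
\mathrm{logit}\, \hat P_{h,i} =
A_h + T_h\,\mathrm{yr}_i + \alpha_h(l_i) + \tau_h(l_i)\,\mathrm{yr}_i +
\delta(l_i) + \chi_{c_i} + \omega_{s_i},
$$

where $\mathrm{yr}_i$ is the scaled collection year, $A_h$ and $T_h$ are the
species' global intercept and temporal trend, $\alpha_h(\cdot)$ and
$\tau_h(\cdot)$ are spatially varying intercept and slope fields indexed by
collection location $l_i$, $\delta(\cdot)$ is a residual spatial field
shared by all species, and $\chi_c$, $\omega_s$ are iid collector and scorer
effects, also shared across species. Sharing $\delta$, $\chi$, $\omega$
across species lets a sparse species borrow information from a well-sampled
one; the species-specific fields keep each host's geography its own.

### Year scaling

The year covariate is centred at 1920 and divided by 100, so $T_h$ and
$\tau_h$ are logit changes *per century*. This is a pure conditioning
choice: uncentred calendar years put the intercept three orders of magnitude
outside the data range and make the Newton steps poorly scaled. Per-year
quantities reported by the package divide by 100 at the end.

### Matern fields via the SPDE construction

Each spatial field is a stationary, isotropic Gaussian random field with
Matern covariance of smoothness $\nu = 1$ (the standard choice for this
model class in two dimensions, where it gives once-differentiable
realizations and the Markov representation below). Rather than working with
dense covariance matrices, the field is represented as a Gaussian Markov
random field on a triangular mesh: the finite-element (piecewise-linear)
discretization of the stochastic partial differential equation whose
stationary solution has exactly this covariance. With lumped mass matrix
$C$, stiffness matrix $G$, $\kappa = \sqrt{8}/\rho$ and
$\tau^2 = 1/(4\pi\kappa^2\sigma^2)$, the node precision is

$$
Q = \tau^2\left(\kappa^4 C + 2\kappa^2 G + G C^{-1} G\right),
$$

sparse and positive definite. `range` $\rho$ follows the usual convention:
the distance at which correlation has decayed to
$\sqrt{8}K_1(\sqrt{8}) \approx 0.14$; `sigma` is the stationary marginal
standard deviation. Observations are tied to node values with barycentric
projector matrices (rows with at most three weights summing to one), so a
piecewise-linear field is evaluated exactly at any point in the mesh hull.

Two deliberate approximations are documented here. The mass matrix is
*lumped* (diagonal), the standard sparsity-preserving variant; and mesh
boundary effects inflate marginal variances near the hull, which is why
`build_mesh()` extends the domain with a buffer ring (default 300 km)
pushing the boundary away from the data. Tests verify the implied
correlation at distance $\rho$ against a dense-inverse oracle to within
$\pm 0.03$ and interior marginal variances to within 15% of $\sigma^2$.

### Mesh construction

`build_mesh()` deduplicates sites closer than `cutoff` (default 25 km,
roughly the georeferencing noise scale of county-centroid coordinates),
Delaunay-triangulates them together with the buffer ring, and bisects long
edges until no edge exceeds `max_edge` (default 150 km interior). There is
no single "correct" resolution; the defaults balance field flexibility
against latent dimension, and all three parameters are user-facing. The
hyperparameter prior-sensitivity pattern (ranges from 68 to 1714 km) is part
of the test suite: the precision stays positive definite and the model
refittable across that span.

### Priors

* Fixed effects $A_h$, $T_h$: zero-mean Gaussians with precision 0.001
  (sd about 31.6 on the logit scale), the conventional vague default.
* iid effect standard deviations: penalized complexity (PC) priors, the
  exponential density implied by $P(\sigma > U_{PC}) = a_{PC}$ with
  $U_{PC} = 1$, $a_{PC} = 0.01$, i.e. rate
  $\lambda = -\ln(0.01) \approx 4.605$. This says a priori that an
  observer is very unlikely to shift the logit by more than $\pm 1$.
* Field ranges: the two-dimensional PC range prior
  $\pi(\rho) = \lambda_\rho \rho^{-2} e^{-\lambda_\rho/\rho}$ with median
  342 km ($\lambda_\rho = -\ln(0.5)\cdot 342 \approx 237.06$) — half the
  prior mass below 342 km, a scale comparable to the synthetic domain's
  short axis.
* Field standard deviations: the PC statement is not pinned down by
  convention for this threshold, so the package defaults to
  $P(\sigma > 1) = 0.01$, deliberately matching the iid-effect prior so
  that spatial and unstructured variance components are penalized at the
  same rate. This is configurable (`pc_prior_field()`).

## Inference: Laplace approximation with empirical Bayes

The model is a latent Gaussian model: Gaussian prior over the latent vector
(fixed effects, field node weights, iid effects), Bernoulli likelihood
through the logit link. Inference proceeds in two nested steps:

1. **Inner step.** At fixed hyperparameters $\theta$ (log range and log sd
   per field, log sd per iid block), the latent posterior is approximated by
   a Gaussian at its mode: damped Newton iteration with sparse Cholesky
   solves, curvature $H = Q_{\mathrm{prior}} + A^\top W A$ with $W$ the
   Bernoulli weights at the mode. Convergence is declared at gradient
   infinity-norm $10^{-6}$, with at most 50 iterations and step halving on
   any objective increase. For a Gaussian likelihood the objective is
   exactly quadratic and one step suffices, which the tests exploit.
2. **Outer step.** The Laplace log marginal likelihood
   $\log p(y\mid\theta) \approx \ell(\hat x) - \tfrac12 \hat x^\top Q \hat x
   + \tfrac12\log|Q| - \tfrac12\log|H|$ plus the log PC prior of $\theta$ is
   maximized by a derivative-free Nelder-Mead simplex in log space, warm
   starting each inner Newton solve from the previous mode, with one
   restart from a perturbed optimum. The result is an empirical-Bayes fit
   at $\hat\theta$; an optional axis grid around $\hat\theta$ with
   normalized weights supports mixture sampling when hyperparameter
   uncertainty matters.

This is deliberately *not* a full nested-Laplace scheme with higher-order
corrections for non-Gaussian marginals: the quantities this analysis reports
— posterior means, central intervals, and sign probabilities of fixed
effects and smooth functionals — are robust to the plain Gaussian
approximation, and the simplification keeps the whole machinery transparent
and testable. The oracle-equivalence test (spatial and iid blocks disabled
reduces the fit to ridge-penalized logistic regression, checked to $10^{-6}$
against an independent IRLS implementation) and the exact conjugate-Gaussian
evidence test pin the implementation down.

Posterior functionals (prevalence surfaces, trend surfaces, sign
probabilities) are computed from latent samples drawn by sparse Cholesky
back-substitution (1000 by default), with empirical quantiles (2.5, 25, 50,
75, 97.5%, linear interpolation). Predictions set collector and scorer
effects to zero — the population-typical specimen — rather than averaging
over observers; a scientist wanting observer-marginal predictions can add
the iid variance explicitly.

## Surfaces and the annualized trend

`predict_prevalence()` evaluates the inverse-logit linear predictor on a
pixel grid (defaults near 60 x 40 km pixels). `svc_slope_surface()` reports
the *annualized* trend as the probability-scale secant
$[\hat P(l, 2020) - \hat P(l, 1895)]/125$ per posterior sample. A "% change
per year" on the probability scale is not uniquely defined for a logistic
curve; the secant over the prediction window is bounded, sample-wise
computable, and reduces to the pointwise derivative when the curve is
near-linear. Hotspot/coldspot maps and the climate regression below both
consume this quantity.

## Climate normals and the post-hoc regression

Monthly temperature and precipitation grids are aggregated into three
four-month seasons (spring Jan-Apr, summer May-Aug, autumn Sep-Dec), as
seasonal means (temperature) and seasonal totals (precipitation). Climate
normals are the mean and standard deviation (denominator $n-1$) over the
historic (1895-1925) and recent (1990-2020) periods, endpoints inclusive; a
pixel-season series needs at least 25 complete years or it is masked. The
twelve climate-change drivers are the recent-minus-historic deltas of
mean and sd for each season and variable.

The post-hoc regression models the fitted annualized trend (in % per year)
at a random subsample of 250 pixels as a linear, Gaussian-error function of
each driver — one simple regression per driver by default, matching the
marginal presentation of such analyses; a joint multiple regression is
available because the marginal and joint readings answer different
questions. Sign probabilities are t-distribution tail areas of the OLS
slope, identical to the flat-prior Bayesian posterior tail. Slopes are per
degree Celsius for temperature drivers and per 100 mm for precipitation
drivers. Subsampling guards against the false confidence of regressing on
arbitrarily many non-independent prediction pixels; pixels are currently
unweighted by the posterior precision of the local trend (a weighting option
is a natural extension).

## Validation

* **AUC** is the normalized Mann-Whitney statistic (ties one half),
  exactly equal to brute-force pair counting (tested on 200 random
  instances).
* **Posterior predictive checks** simulate replicated statuses per
  posterior draw — all model components included — and compare binned
  observed prevalence against the 95% replicate envelope.
* **Out-of-sample evaluation** predicts prevalence at contemporary survey
  populations and reports plant-level AUC (populations expanded into their
  Bernoulli records, the same granularity as the in-sample AUC), a
  logit-logit calibration slope with continuity correction
  $(y + 0.5)/(n + 1)$, and the dispersion contrast between observed and
  predicted population fractions. A population-level rank correlation
  (Spearman) is reported secondarily: a population-level "AUC" is undefined
  without an arbitrary dichotomization, so the rank correlation carries
  that comparison instead.
* **The bias experiment** deletes a configurable fraction of simulated
  records from one region (default the western half-plane), refits, and
  scores sign recovery of each $T_h$, CI coverage of the fixed effects, and
  the correlation between the true and estimated trend surfaces, across
  replicates and bias levels.

## The synthetic-data generator

`simulate_specimens()` draws collection locations uniformly over a
rectangular domain and then *thins* records inside the bias region — the
simplest mechanism that reproduces "a fraction of data missing from one
region" and is exactly verifiable (thinning arithmetic is a binomial count;
records outside the region are untouched). Collection years follow a
power-law recency weight (exponent 1 = uniform; larger mimics the
accelerating accumulation typical of herbaria). Statuses are generated from
the exact SVC model above with true Matern fields sampled from the same SPDE
precision used in inference, and iid collector/scorer effects. Conservative
scores are produced by one-way demotion of liberal positives — never
promotion — consistent with how a cautious scorer would downgrade an
uncertain positive; the paired-score mechanism in real data is not
observable, so demotion is a modelling choice, flagged here, with the rate
configurable (default 0.11).

Default study conditions: three species of 780 specimens each over
1824-2019 on a 1500 x 1000 km domain; global logit trends of +1.8, +1.2,
+0.8 per century from intercepts around 30-50% prevalence (prevalence
roughly doubling over the record); field range 342 km; field sds 1 (spatial
intercept), 0.5 (spatial slope and shared residual); 50 collectors
(sd 0.25) and 25 scorers (sd 0.5); 5-10 seeds scored per specimen. These
are the scales of the motivating herbarium system, chosen once and not
tuned.

What the generator does *not* emulate: georeferencing error beyond the
cutoff-scale site deduplication, imperfect vertical transmission within a
specimen's seed lot, horizontal transmission dynamics, non-uniform
collector home ranges (a spatial-clustering option for scorers is the one
concession, off by default), and real climate topography — the synthetic
climate is a linear trend plus seasonal cycle plus iid noise. Passing tests
therefore demonstrate that the *estimator* recovers the *model's* truth
under realistic sampling artefacts; they do not certify the model's
adequacy for any particular real dataset, which is what the posterior
predictive checks and out-of-sample comparisons are for.

## Numerical choices and degenerate inputs

* Newton damping by step halving; failure to reach the gradient tolerance
  raises a warning carrying the last gradient norm rather than failing
  silently.
* $\sigma = 0$ fields are degenerate precisions; the API refuses them in
  `matern_precision()` (exclude the component instead) while
  `sample_gp_field()` returns the all-zero field, the correct limit.
* Separable logistic data stay bounded because the vague prior is proper.
* Locations outside the mesh hull are an error in the projector (naming
  the offending rows) but a warning-and-drop in the surface/validation
  functions, where partial results are more useful than a refusal.
* Quantiles use linear interpolation (type 7); all randomness flows from
  explicit seeds and every replicate experiment derives per-replicate seeds
  deterministically from a master seed.

## Problem sizes used in the shipped tests

The test-suite experiments run at deliberately modest sizes chosen to make
the statistical assertions sharp while keeping the suite quick to run: the
recovery experiment uses 20 replicates of 3 species x 2000 specimens on a
~300-node mesh with hyperparameters fixed at the generator's true values
(the criterion is about the latent-field and fixed-effect estimator, and
truth is known); the bias experiment runs 10 replicates at 80% deletion;
the concordance experiment 20 replicate pairs at 1000 specimens. Full
empirical-Bayes optimization is exercised separately on single-field and
iid-only models where its behaviour is interpretable.

## Known limitations

* Empirical Bayes at $\hat\theta$ understates hyperparameter uncertainty;
  the optional exploration grid mitigates but does not remove this.
* The secant definition of annualized trend depends (weakly) on the chosen
  endpoint years.
* Scorer effects are statistically confounded with space and time when
  scorers process spatially or temporally clustered batches; the generator
  can simulate this clustering, but the model cannot resolve the
  confounding — only flag it.
* The equirectangular km projection distorts distances at continental
  scales; it is adequate for the few-thousand-km domains intended here and
  is isolated in `project_lonlat()` should a different projection be
  preferred.

## A short end-to-end example

```{r example, eval = FALSE}
cfg <- sim_config(rng_seed = 1)
mesh <- sim_domain_mesh(cfg)
sim <- simulate_specimens(cfg, mesh)

model <- assemble_joint_model(sim$specimens, mesh)
fit <- fit_prevalence_model(model, optimize = FALSE)
tidy(fit)

pg <- pixel_grid(cfg$domain_extent)
autoplot(svc_slope_surface(fit, pg))

climate <- simulate_climate(pg)
deltas <- climate_deltas(seasonal_values(climate))
slopes <- svc_slope_surface(fit, pg, species = "species_1")
posthoc_regression(slopes, deltas)
```
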