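---
title: "Space use and diel activity from camera traps: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space use and diel activity from camera traps: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camoccu)
```

`camoccu` analyses predator–prey camera-trap studies in three linked parts:
single-season occupancy ("space-use") models with imperfect detection, a
two-stage pipeline that feeds prey space-use estimates into a predator model,
and circular-kernel estimation of diel activity overlap. Because presence
data for endangered predators are routinely withheld (camera locations can
be exploited by poachers), the package ships a synthetic study generator
with known ground truth, and every stage of the pipeline is validated
against that truth.

## The occupancy model

Each camera site $i$ has a latent use indicator $z_i \sim
\mathrm{Bernoulli}(\psi_i)$ and, conditional on use, occasion-level
detections $y_{ij} \sim \mathrm{Bernoulli}(z_i\,p_i)$. Both probabilities
take logit-linear covariates:

$$\mathrm{logit}(\psi_i) = \mathbf{x}_i^\top \boldsymbol\beta, \qquad
  \mathrm{logit}(p_i) = \mathbf{w}_i^\top \boldsymbol\alpha .$$

We use the term *space use* rather than occupancy: over a multi-week
camera deployment a wide-ranging predator does not occupy sites in the
closed-population sense, and $\psi$ is better read as the probability that
the species uses the site during the survey. Marginalizing $z_i$ gives the
closed-form site likelihood implemented in `site_likelihood()`:

$$L_i = \psi_i \prod_j p_i^{y_{ij}}(1-p_i)^{1-y_{ij}}
      + (1-\psi_i)\,\mathbf{1}\{\text{no detections at } i\},$$

with masked (inactive-camera) occasions dropped from the product. Detection
covariates are site-level (distances to roads and water do not change
between occasions), so the per-site detection count and the number of
active occasions are sufficient statistics; the tests verify the vectorized
likelihood against explicit latent-state enumeration to $10^{-12}$.

`occu()` fits this model two ways.

* **Maximum likelihood** (`method = "mle"`): BFGS on the joint
  log-likelihood with observed-information standard errors. With `p_fixed =
  1` the detection layer degenerates and the intercept-only estimator
  reduces to the naive proportion of sites with detections, a useful exact
  cross-check.
* **Bayesian** (`method = "mcmc"`, the default): a self-contained
  Metropolis-within-Gibbs sampler. The latent states are drawn from their
  exact full conditional — $z_i = 1$ whenever the site has a detection,
  otherwise $z_i \sim \mathrm{Bernoulli}\big(\mathrm{logit}^{-1}(
  \mathbf{x}_i^\top\boldsymbol\beta + J_i\log(1-p_i))\big)$ — and each
  coefficient takes a single-coordinate random-walk Metropolis step.

Default run settings are 3 chains, 1000 adaptations, 1000 burn-in and
10 000 retained iterations with no thinning. The "adaptation" phase tunes
each proposal scale toward an acceptance rate of 0.3–0.45 (multiplicative
updates every 50 iterations) and is discarded together with the burn-in, so
the retained chains come from a fixed-kernel sampler. Convergence is
monitored with the split-chain Gelman–Rubin statistic; the fit warns when
any monitored parameter has $\widehat R > 1.1$. The rank-normalized variant
of $\widehat R$ is the default (robust to heavy tails); the classical
variant is available via `summary(fit, rank_normalized = FALSE)`. Effective
sample sizes use combined-chain autocorrelations with Geyer's initial
monotone positive-sequence truncation.

Priors are independent Normal(0, 2) on all logit-scale coefficients. The
scale is a deliberate choice: it is diffuse across the plausible
probability range (±2 SD spans probabilities 0.02–0.98) yet proper enough
to stabilize fits with quasi-separation, which arise routinely when a
covariate nearly determines presence at 94 sites. Covariates are z-scored
internally using the analysed sites' means and SDs; the centring constants
are stored in the fit so `predict()` is invariant to the measurement scale.

`summary()` reports, per parameter, the posterior mean, SD, equal-tailed
95% credible limits, $\widehat R$, ESS and `overlap0` — the indicator that
the interval contains zero. A covariate is declared significant when
`overlap0 = 0`; an interval with a bound exactly at zero *contains* zero
(closed-interval convention) and is not significant. The derived rows `psi`
and `p` summarize the posterior of the across-site means of $\psi_i$ and
$p_i$.

## The two-stage pipeline

`tiger_pipeline()` reproduces the full spatial analysis:

1. **Collinearity screen** (`screen_covariates()`): iteratively, while any
   covariate pair has $|r| > 0.7$, the non-protected member with the larger
   VIF is dropped; then any remaining covariate with VIF $> 5$ is dropped.
   VIF is computed as $1/(1-R^2)$ from a direct least-squares regression of
   each column on the rest. The two thresholds are deliberately applied as
   *two phases* because correlation-cutoff and VIF rules select different
   victims in general; both thresholds are configurable, and a `keep` list
   encodes which member of an ecologically interchangeable pair to retain.
2. **Prey stage** (`run_prey_stage()`): one model per prey species with
   constant detection (intercept-only $p$) and space-use covariates
   including a competing-species presence covariate (the summed naive
   detection indicator of the other prey). Species with zero detections
   are skipped and reported. The per-site posterior-mean $\psi$ of each
   prey becomes a covariate column `psi_<species>`.
3. **Predator stage** (`run_tiger_stage()`): a joint $\psi$/$p$ fit with
   prey space use, forest cover and human/livestock photographic counts on
   $\psi$ and landscape features (distance to road and water) on $p$. Prey
   $\psi$ columns are standardized like any other covariate (switchable).
   Stage-1 posterior uncertainty is *not* propagated by default — the
   posterior means enter as fixed covariates, mirroring the two-stage
   design this package implements; treating that as exact is a known
   limitation, and slopes on estimated prey $\psi$ are attenuated relative
   to slopes on the truth. `run_tiger_stage(propagate = TRUE)` offers a
   bootstrap-over-stage-1 alternative: the predator model is refitted over
   several joint posterior draws of the per-site prey $\psi$ and the runs
   are pooled as chains, so the summary reflects both sources of
   variation.
4. **Mapping** (`idw()`): per-site predator $\psi$ is projected onto a
   regular grid by inverse-distance weighting,
   $\hat v(s) = \sum_i d_i^{-k} \psi_i / \sum_i d_i^{-k}$, with power
   $k = 2$ and a 250 m cell by default (the common GIS-tool defaults; the
   method is a weighted average, so grid values are provably bounded by the
   range of site values, and a query at a camera returns its $\psi$
   exactly). Planar coordinates are assumed; the grid is written as an
   ASCII raster.

## Diel activity and overlap

Detection timestamps are converted to radian time of day,
$t = 2\pi\,(\text{seconds since midnight})/86400$. Cameras take a burst of
three photos per trigger; `collapse_bursts()` reduces each burst to one
event (first photo's time, maximum per-photo count), grouping by burst id
when present and otherwise by a 30 s gap rule matching the camera
programming. Because "hourly detections" is ambiguous in field protocols,
`diel_sample()` offers both one-time-per-event (default) and
one-event-per-site-hour thinning.

Activity curves are von Mises kernel density estimates,
$\hat f(t) = \tfrac1n \sum_i e^{\kappa\cos(t-t_i)} / (2\pi I_0(\kappa))$.
The kernel concentration comes from the standard plug-in rule: the sample's
maximum-likelihood concentration $\hat\kappa$ (solving
$I_1(\kappa)/I_0(\kappa) = \bar R$) mapped through
$\big(n\hat\kappa^2\,3I_2(2\hat\kappa)/(4\sqrt\pi I_1(\hat\kappa)^2)\big)^{2/5}$,
times an `adjust` multiplier — 0.8 for the grid estimator and 1.0 for the
point estimator, the conventional small/large-sample tuning. A degenerate
sample (all times equal) caps $\hat\kappa$ with a warning.

The overlap coefficient $\hat\Delta \in [0,1]$ is the area under the
pointwise minimum of the two densities. `Dhat1` integrates $\min(\hat f,
\hat g)$ on a 512-point grid; `Dhat4` averages bounded density ratios at
the observations and is exactly 1 for identical samples. The automatic rule
uses `Dhat1` when the smaller sample has under 50 events and `Dhat4`
otherwise — the conventional switch point, exposed because reports in this
field mix the two estimators without stating sample sizes.

Uncertainty comes from a smoothed bootstrap: each group is resampled from
its *fitted kernel density* (resample the data, add von Mises noise at the
kernel concentration) rather than raw resampling, which avoids tied points
inflating $\hat\Delta$; raw resampling is available. The default interval
is `norm0` — $\hat\Delta \pm z_{0.975}\,\mathrm{sd}(\hat\Delta^*)$, centred
at the original estimate, clamped to $[0,1]$ — with basic and percentile
variants, at 999 resamples. Significance of a pairwise difference in
activity patterns uses a pooled-null randomization test: null samples of
the observed sizes are drawn from the kernel density of the pooled data and
$p = (1 + \#\{\hat\Delta^0 \le \hat\Delta\})/(n_{\mathrm{null}}+1)$, the
add-one rule guaranteeing $p \in (0,1]$.

## The synthetic study generator

`study_config()`/`sim_study()` generate complete studies — covariates,
latent occupancy, detection histories, photo-burst records and diel
clocks — with stored ground truth. The defaults encode the study design the
package targets: 94 cameras at least 1 km apart (uniform on a rectangle
with rejection to enforce spacing, planar geometry) running 21 daily
occasions; six ungulate prey species plus a tiger whose space use tracks
wild pig and gaur space use, livestock counts and forest cover; detection
near 0.74 for the tiger and 0.07–0.45 for prey. Covariate marginals are
lognormal for distances (nonnegative, right-skewed), beta rescaled to the
physical range for canopy (0–100%) and forest cover (0 to the area of a
500 m disc), and negative binomial parameterized by (mean, SD) for
human/livestock counts — mean 53.9 with SD 297.5 for humans, so the
overdispersion of trail traffic is reproduced; an underdispersed (SD² ≤
mean) spec is rejected. Exact distribution families are the generator's own
choice since field summaries report only means and SDs.

Diel clocks are von Mises mixtures: bimodal crepuscular tiger (peaks
18.00–20.00 and 02.00–04.00), broadly diurnal humans (06.00–18.00),
afternoon-peaked livestock (15.00–17.00), and species-appropriate prey
mixtures. The generator's exact pairwise overlap — quadrature of the
minimum of the two mixture densities at 4096 points — is stored as ground
truth for the overlap estimators.

Timestamps are assembled as occasion date + diel clock draw; each event
expands to a 3-photo burst sharing a burst id. The expansion is exactly
invertible: collapsing the records and rebuilding histories reproduces the
simulated matrices bit for bit, and the whole generator is byte-identical
under a fixed seed. What the generator does *not* emulate: spatial
autocorrelation of occupancy, animal movement between sites, within-night
autocorrelation of activity, camera failures, or seasonal drift — so
passing recovery tests demonstrate correctness of the estimators under the
stated model, not robustness to those violations.

## Numerical choices and test scale

All Bernoulli/binomial likelihoods are computed on the log scale with
`log1p`-style guards; the $z$ full conditional is evaluated as
$\mathrm{logit}^{-1}(\mathrm{logit}\psi + J\log(1-p))$, which is stable at
extreme logits. Bessel-function ratios in the bandwidth rule use
exponentially scaled `besselI` to avoid overflow at high concentrations.
Densities are checked to integrate to 1 within $10^{-6}$ on a 512-point
grid.

The validation suite fits tens of thousands of MCMC iterations, so
simulation sizes are chosen to keep the default run short while leaving the
statistical checks well-powered: parameter recovery uses 50 datasets of 200
sites × 10 occasions with chains scaled to 3 × 2000 retained draws;
two-stage significance behaviour uses 50 effect and 50 null replicates at
300 sites; randomization-test calibration uses 200 null replicates with 199
null draws; bootstrap coverage uses 100 replicates at 299 resamples.
Credible-interval coverage is pooled across the three model coefficients
(150 Bernoulli trials) so the 90–99% acceptance band is statistically
meaningful. Production analyses should use the defaults (999 resamples,
3 × 10 000 iterations).

## Known limitations

* Detection probability is site-level; occasion-varying detection
  covariates (weather, moon phase) are out of scope.
* Single-season only: no colonization/extinction dynamics.
* Stage-1 uncertainty is not propagated into the predator model by
  default (see above for the opt-in bootstrap alternative).
* The IDW map is an interpolation of model output, not a spatial model; it
  inherits no uncertainty and assumes planar coordinates.
* The randomization test conditions on the fitted pooled kernel; with very
  small samples its null is only approximately exchangeable.
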