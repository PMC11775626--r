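# camoccu

Camera-trap occupancy, space use and diel activity overlap.

`camoccu` is for ecologists analysing detection/non-detection data from
trail-camera grids in predator–prey systems — the typical design being ~100
cameras a kilometre apart, run for a few weeks, photographing an apex
predator (e.g. tiger), its ungulate prey, and the humans and livestock
sharing the landscape. It answers two questions: *where* does the predator
use space, as a function of prey availability and anthropogenic activity,
and *when* is it active relative to each prey species and to people.

## The models

**Space use.** Each site has a latent use indicator
`z_i ~ Bernoulli(psi_i)` and, given use, occasion detections
`y_ij ~ Bernoulli(z_i * p_i)`, with logit-linear covariates on both
`psi` (space use) and `p` (detection). The marginal site likelihood

    L_i = psi_i * prod_j p_i^y_ij (1 - p_i)^(1 - y_ij)
        + (1 - psi_i) * 1{no detections at i}

is fitted by maximum likelihood or by a built-in adaptive
Metropolis-within-Gibbs sampler (3 chains, 1000 adaptations, 1000 burn-in,
10 000 retained iterations by default; split-chain Gelman–Rubin Rhat with a
1.1 convergence threshold). A covariate is significant when its 95%
credible interval excludes zero (`overlap0 = 0`).

**Two-stage pipeline.** Site covariates are screened for collinearity
(pairwise `|r| > 0.7`, then VIF `> 5`, with a "keep" preference for
ecologically important variables). Each prey species is fitted with
constant detection; the per-site posterior-mean prey `psi` then enters the
predator's space-use model as a covariate, with landscape features
(distance to road/water) on detection. Predicted predator space use is
projected onto a map grid by inverse-distance weighting (power 2, 250 m
cells).

**Diel overlap.** Event times (3-photo bursts collapsed to single events)
are mapped to radians, activity curves are von Mises kernel densities, and
the coefficient of overlapping `Dhat` in [0, 1] is the area under the
pointwise minimum of two curves (`Dhat1` grid-based for small samples,
`Dhat4` at the observations otherwise). Confidence intervals use a 999-way
smoothed bootstrap (`norm0` by default); significance uses a pooled-null
randomization test.

**Synthetic studies.** Because presence data for endangered predators are
often withheld, `sim_study()` generates complete camera-trap studies —
covariates, histories, photo-burst records, diel clocks — with known
ground truth, and the whole pipeline is validated against it.

## Worked example

```r
library(camoccu)
cfg   <- study_config(seed = 42)        # 94 cameras, 21 occasions, 7 species
study <- sim_study(cfg)

events <- collapse_bursts(study$records)
tiger  <- build_history(events, "tiger", study$effort)
tiger
#> Detection history for tiger: 94 sites x 21 occasions, 849 detections, naive occupancy 0.596

fit <- occu(tiger, psi = ~ forest + humans + livestock,
            det = ~ dist_road + dist_water,
            data = study$covariates, seed = 42)
summary(fit)
#> Posterior summary (95% intervals); overlap0 = 0 marks coefficients whose interval excludes zero
#>                  mean    sd    LCL   UCL  Rhat      ESS overlap0
#> psi_(Intercept) 0.518 0.273  0.003 1.074 1.001 3692.728        0
#> psi_forest      1.075 0.374  0.430 1.902 1.001 5104.821        0
#> psi_humans      0.827 0.556  0.023 2.172 1.001 4064.539        0
#> psi_livestock   1.045 0.610  0.062 2.441 1.000 4459.637        0
#> p_(Intercept)   1.027 0.086  0.860 1.201 1.001 2702.804        0
#> p_dist_road     0.222 0.173 -0.113 0.571 1.001 2827.552        1
#> p_dist_water    0.146 0.066  0.024 0.279 1.001 6662.998        0
#> psi             0.594 0.045  0.504 0.680 1.000 6639.084        0
#> p               0.732 0.015  0.701 0.760 1.001 2958.431        0
```

Reading the table: forest cover and livestock counts have credible
intervals excluding zero (`overlap0 = 0`), so tiger space use rises
significantly with both in this synthetic study, while distance to road
does not affect detection (`overlap0 = 1`); the derived rows `psi` and `p`
say tigers used about 59% of sites and were detected on 73% of occasions
at used sites, each with posterior SDs from the full MCMC run.

Diel overlap between tiger and sambar activity:

```r
overlap_est(diel_sample(events, "tiger"), diel_sample(events, "sambar"))
#> Activity overlap Dhat4 = 0.737  (n1 = 849, n2 = 356)
set.seed(42)
overlap_ci(diel_sample(events, "tiger"), diel_sample(events, "sambar"), n_boot = 999)
#> Dhat4 = 0.737, 95% norm0CI = 0.693-0.782 (999 bootstraps)
```

The two species share about three quarters of their activity curves —
the crepuscular tiger overlaps its dusk- and night-active prey far more
than it overlaps diurnal humans (`overlap_est` of tiger vs the human
sample gives ~0.37 under the default generator).

The full two-stage analysis is one call:

```r
pipe <- tiger_pipeline(study, seed = 42)   # screen -> prey fits -> tiger fit -> IDW map
print(pipe)
write_pipeline(pipe, "results/")           # table1.csv, table2.csv, psi_sites.csv, psi_grid.asc, report.json
```

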