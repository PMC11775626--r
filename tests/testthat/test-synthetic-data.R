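test_that("study_config validates its inputs", {
  expect_error(study_config(n_sites = 1), "n_sites")
  expect_error(study_config(n_occasions = 0), "n_occasions")
  expect_error(
    study_config(diel_mixtures = list(
      tiger = list(mu = c(0, pi), kappa = c(2, 2), w = c(0.6, 0.5)))),
    "sum to 1")
  expect_error(
    study_config(diel_mixtures = list(
      tiger = list(mu = 0, kappa = -1, w = 1))),
    "concentrations")
})

test_that("covariate marginals honour their configured moments and bounds", {
  cfg <- study_config(n_sites = 10000, min_spacing = 0,
                      extent = c(1e6, 1e6), seed = 31)
  covs <- sim_covariates(cfg)
  # overdispersed count generator matched to mean 53.9
  expect_lt(abs(mean(covs$humans) - 53.9) / 53.9, 0.10)
  expect_true(all(covs$humans >= 0 & covs$humans == round(covs$humans)))
  expect_true(all(covs$livestock >= 0))
  expect_true(all(covs$canopy >= 0 & covs$canopy <= 100))
  expect_true(all(covs$forest >= 0 & covs$forest <= pi * 0.25))
  expect_true(all(covs$dist_water >= 0 & covs$dist_road >= 0 &
                    covs$dist_settlement >= 0))
  expect_lt(abs(mean(covs$canopy) - 39.52), 1)
  expect_lt(abs(sd(covs$canopy) - 16.28), 1)
})

test_that("degenerate sd = 0 spec gives a constant column", {
  cfg <- study_config(n_sites = 20, seed = 5, min_spacing = 100,
                      covariate_generators = list(
                        canopy = list(dist = "beta_scaled", mean = 40, sd = 0,
                                      min = 0, max = 100),
                        humans = list(dist = "nbinom", mean = 5, sd = 0)))
  covs <- sim_covariates(cfg)
  expect_true(all(covs$canopy == 40))
  expect_true(all(covs$humans == 5))
})

test_that("underdispersed negative-binomial specs are rejected", {
  cfg <- study_config(n_sites = 10, min_spacing = 100, seed = 1,
                      covariate_generators = list(
                        humans = list(dist = "nbinom", mean = 10, sd = 2)))
  expect_error(sim_covariates(cfg), "overdispersion")
})

test_that("generator is deterministic given the seed, to the byte", {
  cfg <- tiny_config(seed = 13)
  s1 <- sim_study(cfg); s2 <- sim_study(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write.csv(s1$records, f1, row.names = FALSE)
  write.csv(s2$records, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$covariates, s2$covariates)
  expect_identical(s1$truth, s2$truth)
})

test_that("camera sites respect the minimum spacing", {
  covs <- sim_covariates(study_config(seed = 3))
  d <- as.matrix(dist(covs[, c("x", "y")]))
  diag(d) <- Inf
  expect_gte(min(d), 1000)
})

test_that("saturated and empty logit regimes give all-ones / all-zero histories", {
  base <- tiny_config()
  cfg1 <- tiny_config()
  cfg1$occupancy_coefs$tiger <- c("(Intercept)" = 20)
  cfg1$detection_coefs$tiger <- c("(Intercept)" = 20)
  h1 <- sim_histories(cfg1)$histories$tiger
  expect_true(all(h1$y == 1))
  cfg0 <- tiny_config()
  cfg0$occupancy_coefs$tiger <- c("(Intercept)" = -20)
  h0 <- sim_histories(cfg0)$histories$tiger
  expect_true(all(h0$y == 0))
})

test_that("histories are Bernoulli-consistent with the latent states", {
  sim <- sim_histories(tiny_config(seed = 21))
  for (sp in names(sim$histories)) {
    y <- sim$histories[[sp]]$y
    z <- sim$truth$z[, sp]
    expect_true(all(rowSums(y)[z == 0] == 0))
    expect_true(all(sim$truth$psi[, sp] > 0 & sim$truth$psi[, sp] < 1))
  }
})

test_that("naive occupancy matches its closed form under a known regime", {
  # psi = 0.54, p = 0.74, 500 x 14: E[naive] = psi * (1 - (1-p)^14)
  cfg <- study_config(
    n_sites = 500, n_occasions = 14, seed = 17, min_spacing = 0,
    extent = c(1e6, 1e6), species_list = "tiger",
    occupancy_coefs = list(tiger = c("(Intercept)" = qlogis(0.54))),
    detection_coefs = list(tiger = c("(Intercept)" = qlogis(0.74))))
  h <- sim_histories(cfg)$histories$tiger
  naive <- mean(rowSums(h$y) > 0)
  expected <- 0.54 * (1 - (1 - 0.74)^14)
  se <- sqrt(expected * (1 - expected) / 500)
  expect_lt(abs(naive - expected), 3 * se)
})

test_that("naive occupancy cannot exceed true occupancy on average", {
  biases <- replicate(30, {
    cfg <- study_config(n_sites = 100, n_occasions = 5,
                        seed = sample.int(1e6, 1), min_spacing = 0,
                        extent = c(1e5, 1e5), species_list = "sp",
                        occupancy_coefs = list(sp = c("(Intercept)" = 0.2)),
                        detection_coefs = list(sp = c("(Intercept)" = -0.5)))
    sim <- sim_histories(cfg)
    mean(rowSums(sim$histories$sp$y) > 0) - mean(sim$truth$psi[, "sp"])
  })
  expect_lt(mean(biases), 0)
})

test_that("diel mixture draws match the configured shape", {
  cfg <- tiny_config(seed = 41)
  # near point mass
  cfg$diel_mixtures$deer <- list(mu = 1, kappa = 400, w = 1)
  x <- sim_diel(cfg, c(deer = 5000))$deer
  expect_true(all(x >= 0 & x < 2 * pi))
  circ_sd <- sqrt(-2 * log(sqrt(mean(cos(x))^2 + mean(sin(x))^2)))
  expect_lt(circ_sd, 0.1)
  # antipodal symmetric mixture: resultant near zero
  cfg$diel_mixtures$pig <- list(mu = c(0, pi), kappa = c(5, 5), w = c(0.5, 0.5))
  y <- sim_diel(cfg, c(pig = 10000))$pig
  expect_lt(sqrt(mean(cos(y))^2 + mean(sin(y))^2), 0.03)
  # empty sample allowed
  expect_length(sim_diel(cfg, c(deer = 0))$deer, 0)
})

test_that("default tiger activity is bimodal crepuscular (18-20 h and 2-4 h)", {
  cfg <- study_config(seed = 55)
  x <- sim_diel(cfg, c(tiger = 10000))$tiger
  hrs <- x * 24 / (2 * pi)
  counts <- table(cut(hrs, breaks = seq(0, 24, 2)))
  top2 <- names(sort(counts, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("(18,20]", "(2,4]"))
  # mixture component proportions converge to the weights
  # (classify draws by the nearest component mean: boundaries 11 h and 23 h)
  evening <- mean(hrs > 11 & hrs <= 23)
  expect_lt(abs(evening - cfg$diel_mixtures$tiger$w[1]), 0.03)
})

test_that("emit_records expands each event into one 3-photo burst", {
  cfg <- tiny_config(seed = 9)
  sim <- sim_histories(cfg)
  one <- detection_history(matrix(c(1, rep(0, 9)), 2, 5), c("A", "B"), "tiger")
  rec <- emit_records(list(tiger = one), list(tiger = pi),
                      data.frame(site = c("A", "B")), cfg)
  expect_equal(nrow(rec), 3)
  expect_length(unique(rec$burst_id), 1)
  expect_equal(unique(rec$site_id), "A")
  # empty history: header-only table
  none <- detection_history(matrix(0, 2, 5), c("A", "B"), "tiger")
  rec0 <- emit_records(list(tiger = none), list(tiger = numeric(0)),
                       data.frame(site = c("A", "B")), cfg)
  expect_equal(nrow(rec0), 0)
  expect_named(rec0, c("site_id", "species", "datetime", "count", "burst_id"))
})

test_that("records round-trip through burst collapse and history building", {
  st <- sim_study(tiny_config(seed = 77))
  events <- collapse_bursts(st$records)
  for (sp in names(st$histories)) {
    rebuilt <- build_history(events, sp, st$effort)
    expect_identical(rebuilt$y, st$histories[[sp]]$y)
  }
})

test_that("true mixture overlap is exact for identical specs and in [0,1]", {
  cfg <- study_config(seed = 1)
  m <- cfg$diel_mixtures$tiger
  expect_lt(abs(true_overlap(m, m) - 1), 1e-9)
  tr <- sim_histories(tiny_config())$truth$diel_overlap
  expect_true(all(diag(tr) == 1))
  expect_true(all(tr >= 0 & tr <= 1))
  expect_equal(tr, t(tr))
})

test_that("write_study emits readable plain-text artefacts", {
  st <- sim_study(tiny_config(seed = 3))
  dir <- tempfile()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "records.csv")))
  covs <- read.csv(file.path(dir, "covariates.csv"))
  expect_equal(nrow(covs), st$config$n_sites)
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg_back$seed, st$config$seed)
})
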