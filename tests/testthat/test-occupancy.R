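test_that("site likelihood matches hand arithmetic and handles masks", {
  expect_equal(site_likelihood(c(0, 0), 0.5, 0.5), 0.625)
  expect_equal(site_likelihood(c(1, 0), 1, 0.3), 0.21)
  # masked occasions are excluded from the product
  expect_equal(site_likelihood(c(1, NA, 0), 0.8, 0.4),
               site_likelihood(c(1, 0), 0.8, 0.4))
  expect_equal(site_likelihood(c(NA, NA), 0.3, 0.9), 1)  # no information
})

test_that("site likelihood equals explicit latent-state enumeration", {
  set.seed(101)
  for (i in 1:200) {
    J <- sample(1:4, 1)
    y <- rbinom(J, 1, 0.4)
    if (runif(1) < 0.3) y[sample(J, 1)] <- NA
    psi <- runif(1, 0.01, 0.99)
    p <- runif(J, 0.01, 0.99)
    expect_equal(site_likelihood(y, psi, p), enum_site_likelihood(y, psi, p),
                 tolerance = 1e-14)
  }
})

test_that("MLE with detection fixed at 1 returns the naive proportion", {
  y <- matrix(0, 94, 5)
  y[seq_len(46), 1] <- 1
  fit <- occu(y, method = "mle", p_fixed = 1)
  expect_equal(unname(plogis(coef(fit))), 46 / 94, tolerance = 1e-6)
})

test_that("all-detection data push the MLE to the upper boundary", {
  y <- matrix(1, 40, 6)
  fit <- occu(y, method = "mle")
  expect_gt(plogis(coef(fit)[1]), 0.95)
  expect_gt(plogis(coef(fit)[2]), 0.95)
})

test_that("the MLE recovers known psi and p on a large simulated study", {
  cfg <- study_config(n_sites = 500, n_occasions = 14, seed = 23,
                      min_spacing = 0, extent = c(1e6, 1e6),
                      species_list = "sp",
                      occupancy_coefs = list(sp = c("(Intercept)" = qlogis(0.54))),
                      detection_coefs = list(sp = c("(Intercept)" = qlogis(0.74))))
  h <- sim_histories(cfg)$histories$sp
  fit <- occu(h, method = "mle")
  expect_true(fit$converged)
  expect_lt(abs(plogis(coef(fit)[1]) - 0.54), 0.03)
  expect_lt(abs(plogis(coef(fit)[2]) - 0.74), 0.03)
})

test_that("identical seeds give identical chains; seeds differ otherwise", {
  y <- matrix(rbinom(60 * 6, 1, 0.3), 60, 6)
  f1 <- occu_fast(y, seed = 5)
  f2 <- occu_fast(y, seed = 5)
  f3 <- occu_fast(y, seed = 6)
  expect_identical(f1$chains, f2$chains)
  expect_false(identical(f1$chains, f3$chains))
})

test_that("with fully masked data the posterior reproduces the prior", {
  y <- matrix(NA_real_, 30, 3)
  fit <- occu(y, method = "mcmc", chains = 2, adapt = 500, burnin = 500,
              iter = 5000, seed = 12)
  draws <- posterior_draws(fit)[, "psi_(Intercept)"]
  # KS distance against the Normal(0, 2) prior
  ks <- max(abs(ecdf(draws)(sort(draws)) - pnorm(sort(draws), 0, 2)))
  expect_lt(ks, 0.05)
  expect_lt(abs(mean(draws)), 0.15)
  expect_lt(abs(sd(draws) - 2), 0.2)
})

test_that("posterior means agree with the MLE on a well-identified dataset", {
  cfg <- study_config(n_sites = 300, n_occasions = 10, seed = 31,
                      min_spacing = 0, extent = c(1e6, 1e6),
                      species_list = "sp",
                      covariate_generators = list(
                        cov1 = list(dist = "normal", mean = 0, sd = 1)),
                      occupancy_coefs = list(sp = c("(Intercept)" = 0.3, cov1 = 0.8)),
                      detection_coefs = list(sp = c("(Intercept)" = 0)))
  sim <- sim_histories(cfg)
  h <- sim$histories$sp
  dat <- sim$covariates
  mle <- occu(h, psi = ~cov1, data = dat, method = "mle")
  bay <- occu(h, psi = ~cov1, data = dat, method = "mcmc",
              chains = 3, adapt = 500, burnin = 500, iter = 2000, seed = 8,
              priors = list(mean = 0, sd = 10))
  s <- summary(bay)
  for (nm in names(coef(mle)))
    expect_lt(abs(s[nm, "mean"] - coef(mle)[nm]), 2 * s[nm, "sd"])
})

test_that("summary flags interval overlap with zero by the closed-interval rule", {
  tab <- data.frame(LCL = c(0.058, -0.625, 0.373, -0.286, 0),
                    UCL = c(4.604, 2.211, 2.591, 4.384, 1.2))
  rownames(tab) <- c("livestock", "forest", "gaur", "human", "touching")
  flags <- is_significant(tab)
  expect_true(flags[["livestock"]])   # (0.058, 4.604) excludes zero
  expect_false(flags[["forest"]])     # (-0.625, 2.211) contains zero
  expect_true(flags[["gaur"]])
  expect_false(flags[["human"]])
  expect_false(flags[["touching"]])   # bound exactly at zero: contains it
})

test_that("Rhat is near 1 for iid chains and large for disjoint chains", {
  set.seed(3)
  good <- matrix(rnorm(3e4), 1e4, 3)
  expect_lt(rhat(good), 1.01)
  expect_lt(rhat(good, rank_normalized = FALSE), 1.01)
  bad <- cbind(rnorm(500), rnorm(500) + 5)
  expect_gt(rhat(bad), 1.5)
  expect_equal(as.numeric(rhat(matrix(1, 100, 3))), 1)
  expect_true(attr(rhat(matrix(1, 100, 3)), "constant"))
})

test_that("ESS tracks the AR(1) theoretical value and iid draws", {
  set.seed(14)
  iid <- matrix(rnorm(2e4), 1e4, 2)
  expect_gt(ess(iid), 0.85 * 2e4)
  phi <- 0.6
  ar <- replicate(2, as.numeric(arima.sim(list(ar = phi), 2e4)))
  theory <- (1 - phi) / (1 + phi) * length(ar)
  expect_lt(abs(ess(ar) - theory) / theory, 0.25)
  # agrees broadly with coda's estimator
  expect_lt(abs(ess(ar) - sum(apply(ar, 2, function(ch)
    coda::effectiveSize(coda::mcmc(ch))))) / theory, 0.4)
})

test_that("predicted psi matches per-draw recomputation and logistic monotonicity", {
  set.seed(9)
  dat <- data.frame(cov1 = rnorm(25))
  y <- matrix(rbinom(25 * 6, 1, 0.5), 25, 6)
  fit <- occu_fast(y, psi = ~cov1, data = dat, seed = 3)
  pr <- predict(fit, type = "psi")
  expect_true(all(pr$mean > 0 & pr$mean < 1))
  # brute-force recomputation on the first 5 sites
  draws <- posterior_draws(fit)
  X <- model.matrix(~cov1, standardize_covs(dat, fit$center, fit$scale)$data)
  for (i in 1:5) {
    manual <- mean(plogis(draws[, 1] + draws[, 2] * X[i, 2]))
    expect_equal(pr$mean[i], manual, tolerance = 1e-12)
  }
  # a positive slope means larger covariate -> larger psi
  b <- coef(fit)
  ord <- order(dat$cov1)
  if (b[2] > 0) expect_true(all(diff(predict(fit)$mean[ord]) >= -1e-12))
})

test_that("simulate() reproduces the fitted data-generating process", {
  y <- matrix(rbinom(200 * 8, 1, rep(rbinom(200, 1, 0.6) * 0.5, 8)), 200, 8)
  y[3, 2] <- NA
  fit <- occu(y, method = "mle")
  sims <- simulate(fit, nsim = 20, seed = 2)
  expect_length(sims, 20)
  expect_true(all(vapply(sims, function(s) is.na(s[3, 2]), logical(1))))
  naive_sim <- mean(vapply(sims, function(s) mean(rowSums(s, na.rm = TRUE) > 0),
                           numeric(1)))
  expect_lt(abs(naive_sim - mean(rowSums(y, na.rm = TRUE) > 0)), 0.08)
})

test_that("standardization metadata make prediction covariate-scale invariant", {
  set.seed(7)
  dat <- data.frame(cov1 = rnorm(40, 100, 15))
  y <- matrix(rbinom(40 * 5, 1, 0.4), 40, 5)
  fit <- occu(y, psi = ~cov1, data = dat, method = "mle")
  p1 <- predict(fit, newdata = dat)
  p2 <- predict(fit, newdata = dat[1:10, , drop = FALSE])
  expect_equal(p1$estimate[1:10], p2$estimate)
})
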