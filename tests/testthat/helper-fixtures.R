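# short MCMC settings for unit tests (acceptance tests set their own)
fast_mcmc <- list(chains = 2, adapt = 300, burnin = 300, iter = 1000)

occu_fast <- function(history, ..., seed = 99) {
  occu(history, ..., method = "mcmc", chains = fast_mcmc$chains,
       adapt = fast_mcmc$adapt, burnin = fast_mcmc$burnin,
       iter = fast_mcmc$iter, seed = seed)
}

# tiny study configuration: 12 sites, 3 species, quick to simulate
tiny_config <- function(seed = 7, n_sites = 12, n_occasions = 5) {
  study_config(
    n_sites = n_sites, n_occasions = n_occasions, seed = seed,
    species_list = c("deer", "pig", "tiger"),
    occupancy_coefs = list(
      deer = c("(Intercept)" = 0.3, canopy = 0.4),
      pig = c("(Intercept)" = 0.2, forest = 0.5),
      tiger = c("(Intercept)" = 0, forest = 0.5, psi_pig = 1)),
    detection_coefs = list(
      deer = c("(Intercept)" = 0),
      pig = c("(Intercept)" = -0.2),
      tiger = c("(Intercept)" = 1)),
    diel_mixtures = list(
      deer = list(mu = pi / 2, kappa = 2, w = 1),
      pig = list(mu = pi, kappa = 2, w = 1),
      tiger = list(mu = c(pi / 4, 5 * pi / 4), kappa = c(3, 3), w = c(0.5, 0.5)),
      human = list(mu = pi, kappa = 1, w = 1),
      livestock = list(mu = 4, kappa = 2, w = 1)),
    min_spacing = 200, extent = c(5000, 5000))
}

# brute-force site likelihood by explicit latent-state enumeration
enum_site_likelihood <- function(y, psi, p) {
  p <- rep_len(p, length(y))
  obs <- !is.na(y)
  y <- y[obs]; p <- p[obs]
  lik <- 0
  for (z in c(0, 1)) {
    pr_y <- prod(ifelse(y == 1, z * p, 1 - z * p))
    lik <- lik + pr_y * ifelse(z == 1, psi, 1 - psi)
  }
  lik
}
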