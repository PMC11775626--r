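#' Configuration for a synthetic camera-trap study
#'
#' Defines the full data-generating process for a synthetic predator-prey
#' camera-trap study: site layout, per-site covariate distributions,
#' logit-scale occupancy and detection coefficients per species, von Mises
#' diel-activity mixtures, and overdispersed human/livestock photographic
#' counts. Defaults emulate a 94-camera lowland-Nepal tiger study: cameras at
#' least 1 km apart running 21 daily occasions, six ungulate prey species,
#' strongly overdispersed human counts (mean 53.9, sd 297.5) and livestock
#' counts (mean 2.9, sd 12.8), canopy cover 39.52 +/- 16.28 %, forest cover
#' 0.712 +/- 0.134 km2 within a 500 m radius, and mean distances to
#' settlement/road/water of 3745.6/1091.5/2785.3 m. The tiger is bimodally
#' crepuscular (activity peaks at 18.00-20.00 and 02.00-04.00), humans are
#' diurnal (06.00-18.00) and livestock peak at 15.00-17.00.
#'
#' Occupancy coefficients may reference the column `psi_<species>` of any
#' species listed earlier, so a predator's space use can be driven by the
#' (standardized) true space use of its prey; species are simulated in list
#' order.
#'
#' @param n_sites number of camera sites (>= 2; default 94).
#' @param n_occasions sampling occasions per site (>= 1; default 21 daily
#'   occasions).
#' @param seed integer seed governing every draw of the generator.
#' @param species_list character vector naming the modelled species, in
#'   simulation order (prey before predator).
#' @param occupancy_coefs named list (per species) of named logit-scale
#'   coefficient vectors; names must be `"(Intercept)"`, covariate columns,
#'   or `psi_<earlier species>`.
#' @param detection_coefs named list (per species) of named logit-scale
#'   detection coefficients (prey default: intercept only).
#' @param covariate_generators named list of marginal distribution specs:
#'   `list(dist = "lognormal"|"beta_scaled"|"nbinom"|"normal", mean, sd,
#'   min, max)`; `sd = 0` gives a constant column.
#' @param diel_mixtures named list (species, plus `"human"`/`"livestock"`)
#'   of von Mises mixture specs `list(mu=, kappa=, w=)` in radians.
#' @param min_spacing minimum pairwise distance between cameras in metres
#'   (default 1000).
#' @param extent numeric length-2, east-west and north-south extent of the
#'   rectangular study area in metres.
#' @return an object of class `"study_config"`.
#' @export
study_config <- function(n_sites = 94, n_occasions = 21, seed = 1,
                         species_list = c("barking_deer", "blue_bull", "chital",
                                          "gaur", "sambar", "wild_pig", "tiger"),
                         occupancy_coefs = NULL, detection_coefs = NULL,
                         covariate_generators = NULL, diel_mixtures = NULL,
                         min_spacing = 1000, extent = c(30000, 15000)) {
  if (n_sites < 2) stop("n_sites must be >= 2")
  if (n_occasions < 1) stop("n_occasions must be >= 1")
  h <- function(x) 2 * pi * x / 24   # clock hour -> radians

  if (is.null(covariate_generators)) covariate_generators <- list(
    dist_water      = list(dist = "lognormal", mean = 2785.3, sd = 2554.6),
    dist_road       = list(dist = "lognormal", mean = 1091.46, sd = 1507.6),
    dist_settlement = list(dist = "lognormal", mean = 3745.6, sd = 2110.1),
    canopy          = list(dist = "beta_scaled", mean = 39.52, sd = 16.28,
                           min = 0, max = 100),
    # forest cover within a 500 m disc, km2 (upper bound pi * 0.5^2)
    forest          = list(dist = "beta_scaled", mean = 0.712, sd = 0.134,
                           min = 0, max = pi * 0.25),
    humans          = list(dist = "nbinom", mean = 53.9, sd = 297.5),
    livestock       = list(dist = "nbinom", mean = 2.9, sd = 12.8))

  # prey intercepts chosen so baseline psi/p match a Terai prey community
  # (space use 0.37-0.60, detection 0.07-0.45); the tiger tracks wild pig
  # and gaur space use, livestock counts, and forest cover.
  # the three prey entering the predator model are driven by distinct
  # covariates so their space-use columns are identifiable in stage 2
  if (is.null(occupancy_coefs)) occupancy_coefs <- list(
    barking_deer = c("(Intercept)" = stats::qlogis(0.540), canopy = 0.4),
    blue_bull    = c("(Intercept)" = stats::qlogis(0.579), dist_settlement = 0.6),
    chital       = c("(Intercept)" = stats::qlogis(0.497), forest = 0.4),
    gaur         = c("(Intercept)" = stats::qlogis(0.367), canopy = 0.7),
    sambar       = c("(Intercept)" = stats::qlogis(0.600), canopy = 0.5),
    wild_pig     = c("(Intercept)" = stats::qlogis(0.579), dist_road = -0.5,
                     humans = 0.4),
    tiger        = c("(Intercept)" = 0.236, forest = 0.648, humans = 0.3,
                     livestock = 0.7, psi_blue_bull = 0.429, psi_gaur = 1.370,
                     psi_wild_pig = 1.859))
  if (is.null(detection_coefs)) detection_coefs <- list(
    barking_deer = c("(Intercept)" = stats::qlogis(0.415)),
    blue_bull    = c("(Intercept)" = stats::qlogis(0.067)),
    chital       = c("(Intercept)" = stats::qlogis(0.415)),
    gaur         = c("(Intercept)" = stats::qlogis(0.196)),
    sambar       = c("(Intercept)" = stats::qlogis(0.284)),
    wild_pig     = c("(Intercept)" = stats::qlogis(0.454)),
    tiger        = c("(Intercept)" = stats::qlogis(0.740),
                     dist_road = 0.3, dist_water = 0.2))

  if (is.null(diel_mixtures)) diel_mixtures <- list(
    tiger        = list(mu = h(c(19, 3)), kappa = c(3, 3), w = c(0.55, 0.45)),
    sambar       = list(mu = h(c(18, 3, 9)), kappa = c(3, 2.5, 2), w = c(0.45, 0.3, 0.25)),
    wild_pig     = list(mu = h(c(18, 6)), kappa = c(2, 0.5), w = c(0.7, 0.3)),
    chital       = list(mu = h(c(8, 17)), kappa = c(2, 2), w = c(0.5, 0.5)),
    barking_deer = list(mu = h(c(9, 18)), kappa = c(3, 3), w = c(0.6, 0.4)),
    blue_bull    = list(mu = h(c(10, 16)), kappa = c(2, 2), w = c(0.5, 0.5)),
    gaur         = list(mu = h(c(17, 5)), kappa = c(2, 1.5), w = c(0.6, 0.4)),
    human        = list(mu = h(12), kappa = 1.2, w = 1),
    livestock    = list(mu = h(16), kappa = 3, w = 1))

  for (sp in names(diel_mixtures)) {
    mx <- diel_mixtures[[sp]]
    if (abs(sum(mx$w) - 1) > 1e-12)
      stop("diel mixture weights for '", sp, "' do not sum to 1")
    if (any(mx$kappa <= 0)) stop("diel mixture concentrations for '", sp, "' must be > 0")
  }
  for (sp in species_list) {
    if (is.null(occupancy_coefs[[sp]])) stop("no occupancy coefficients for '", sp, "'")
    if (is.null(detection_coefs[[sp]])) stop("no detection coefficients for '", sp, "'")
  }

  structure(list(n_sites = n_sites, n_occasions = n_occasions, seed = seed,
                 species_list = species_list,
                 occupancy_coefs = occupancy_coefs,
                 detection_coefs = detection_coefs,
                 covariate_generators = covariate_generators,
                 diel_mixtures = diel_mixtures,
                 min_spacing = min_spacing, extent = extent),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("Synthetic camera-trap study configuration\n")
  cat(sprintf("  %d sites (>= %g m apart), %d occasions, seed %d\n",
              x$n_sites, x$min_spacing, x$n_occasions, x$seed))
  cat("  species:", paste(x$species_list, collapse = ", "), "\n")
  invisible(x)
}

## one covariate column from a marginal spec
.draw_covariate <- function(spec, n) {
  if (spec$sd == 0) {
    x <- rep(spec$mean, n)
    return(if (identical(spec$dist, "nbinom")) round(x) else x)
  }
  switch(spec$dist,
    lognormal = {
      s2 <- log(1 + (spec$sd / spec$mean)^2)
      stats::rlnorm(n, meanlog = log(spec$mean) - s2 / 2, sdlog = sqrt(s2))
    },
    beta_scaled = {
      rng <- spec$max - spec$min
      m <- (spec$mean - spec$min) / rng
      v <- (spec$sd / rng)^2
      if (v >= m * (1 - m)) stop("beta_scaled spec: sd too large for the (min, max) range")
      a <- m * (m * (1 - m) / v - 1)
      spec$min + rng * stats::rbeta(n, a, a * (1 - m) / m)
    },
    nbinom = {
      if (spec$sd^2 <= spec$mean)
        stop("negative-binomial spec requires sd^2 > mean (overdispersion)")
      size <- spec$mean^2 / (spec$sd^2 - spec$mean)
      stats::rnbinom(n, size = size, mu = spec$mean)
    },
    normal = stats::rnorm(n, spec$mean, spec$sd),
    stop("unknown covariate distribution '", spec$dist, "'"))
}

## rectangle coordinates with a minimum-spacing rejection rule
.draw_coords <- function(n, extent, min_spacing, max_tries = 20000) {
  xy <- matrix(NA_real_, n, 2)
  got <- 0L
  for (t in seq_len(max_tries)) {
    cand <- c(stats::runif(1, 0, extent[1]), stats::runif(1, 0, extent[2]))
    if (got == 0L ||
        min(sqrt((xy[seq_len(got), 1] - cand[1])^2 +
                 (xy[seq_len(got), 2] - cand[2])^2)) >= min_spacing) {
      got <- got + 1L
      xy[got, ] <- cand
      if (got == n) return(xy)
    }
  }
  stop("could not place ", n, " sites >= ", min_spacing,
       " m apart in the study rectangle; enlarge `extent`")
}

#' Generate per-site covariates for a synthetic study
#'
#' Draws camera coordinates (uniform on the study rectangle, rejected to
#' enforce the minimum spacing) and one column per configured covariate
#' marginal: lognormal distances, beta-rescaled canopy/forest cover, and
#' negative-binomial human/livestock photographic counts parameterized by
#' (mean, sd).
#'
#' @param config a [study_config()].
#' @return data.frame with one row per site: `site`, `x`, `y` (metres) and
#'   the covariate columns.
#' @export
sim_covariates <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  n <- config$n_sites
  xy <- .draw_coords(n, config$extent, config$min_spacing)
  out <- data.frame(site = sprintf("S%03d", seq_len(n)), x = xy[, 1], y = xy[, 2])
  for (nm in names(config$covariate_generators))
    out[[nm]] <- .draw_covariate(config$covariate_generators[[nm]], n)
  out
}

#' Simulate detection histories with known truth
#'
#' Standardizes the covariates, applies each species' logit-linear occupancy
#' and detection coefficients, draws latent occupancy `z ~ Bernoulli(psi)`
#' and occasion-level detections `y ~ Bernoulli(z * p)`. Species are
#' processed in `species_list` order and each species' true (standardized)
#' psi becomes available to later species as covariate `psi_<species>`.
#'
#' @param config a [study_config()].
#' @param covs covariate table from [sim_covariates()]; generated if `NULL`.
#' @return list with `histories` (named list of `detection_history`
#'   objects), `truth` (list: `psi`, `p`, `z` matrices sites x species, the
#'   coefficient vectors, and `diel_overlap`, the exact pairwise overlap of
#'   the configured diel mixtures), and `covariates`.
#' @export
sim_histories <- function(config, covs = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(covs)) covs <- sim_covariates(config)
  set.seed(config$seed + 1)
  n <- config$n_sites; J <- config$n_occasions
  num <- covs[setdiff(names(covs), c("site", "x", "y"))]
  std <- standardize_covs(num)$data
  sp_all <- config$species_list
  psi_m <- p_m <- z_m <- matrix(NA_real_, n, length(sp_all),
                                dimnames = list(covs$site, sp_all))
  histories <- list()
  for (sp in sp_all) {
    bc <- config$occupancy_coefs[[sp]]
    ac <- config$detection_coefs[[sp]]
    eta_psi <- .apply_coefs(bc, std, sp)
    eta_p <- .apply_coefs(ac, std, sp)
    psi <- stats::plogis(eta_psi); p <- stats::plogis(eta_p)
    z <- stats::rbinom(n, 1, psi)
    y <- matrix(stats::rbinom(n * J, 1, rep(z * p, J)), n, J)
    histories[[sp]] <- detection_history(y, covs$site, sp)
    psi_m[, sp] <- psi; p_m[, sp] <- p; z_m[, sp] <- z
    # expose this species' standardized true psi to later species
    std[[paste0("psi_", sp)]] <- as.numeric(scale(psi))
    if (stats::sd(psi) == 0) std[[paste0("psi_", sp)]] <- rep(0, n)
  }
  truth <- list(psi = psi_m, p = p_m, z = z_m,
                occupancy_coefs = config$occupancy_coefs,
                detection_coefs = config$detection_coefs,
                diel_overlap = .true_overlap_matrix(config$diel_mixtures))
  list(histories = histories, truth = truth, covariates = covs)
}

## evaluate a named coefficient vector against standardized covariates
.apply_coefs <- function(coefs, std, sp) {
  eta <- rep(0, nrow(std))
  for (nm in names(coefs)) {
    if (nm == "(Intercept)") eta <- eta + coefs[[nm]]
    else if (!is.null(std[[nm]])) eta <- eta + coefs[[nm]] * std[[nm]]
    else stop("coefficient '", nm, "' for species '", sp,
              "' matches no covariate column")
  }
  eta
}

## mixture density and exact pairwise overlap of configured diel mixtures
.mixture_density <- function(mix, at) {
  f <- rep(0, length(at))
  for (k in seq_along(mix$w))
    f <- f + mix$w[k] * dvonmises(at, mix$mu[k], mix$kappa[k])
  f
}

#' Exact overlap of two von Mises mixture densities
#'
#' The true coefficient of overlapping Delta: the integral over the circle
#' of the pointwise minimum of the two mixture densities, by midpoint
#' quadrature.
#'
#' @param mix1,mix2 mixture specs `list(mu=, kappa=, w=)` in radians.
#' @param n_grid quadrature points (default 4096).
#' @return Delta in `[0, 1]`; 1 for identical mixtures.
#' @export
true_overlap <- function(mix1, mix2, n_grid = 4096) {
  at <- (seq_len(n_grid) - 0.5) * 2 * pi / n_grid
  sum(pmin(.mixture_density(mix1, at), .mixture_density(mix2, at))) * 2 * pi / n_grid
}

.true_overlap_matrix <- function(mixtures) {
  k <- length(mixtures)
  m <- diag(1, k)
  dimnames(m) <- list(names(mixtures), names(mixtures))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    m[i, j] <- m[j, i] <- true_overlap(mixtures[[i]], mixtures[[j]])
  m
}

#' Draw diel activity times from the configured mixtures
#'
#' @param config a [study_config()].
#' @param n_events named integer vector: events per species (names must be
#'   present in `config$diel_mixtures`). Zero gives an empty sample.
#' @return named list of radian samples in `[0, 2*pi)`.
#' @export
sim_diel <- function(config, n_events) {
  stopifnot(inherits(config, "study_config"), !is.null(names(n_events)))
  set.seed(config$seed + 2)
  out <- list()
  for (sp in names(n_events)) {
    mix <- config$diel_mixtures[[sp]]
    if (is.null(mix)) stop("no diel mixture configured for '", sp, "'")
    n <- n_events[[sp]]
    if (n == 0) { out[[sp]] <- numeric(0); next }
    comp <- sample.int(length(mix$w), n, replace = TRUE, prob = mix$w)
    x <- numeric(n)
    for (k in seq_along(mix$w)) {
      idx <- comp == k
      if (any(idx)) x[idx] <- rvonmises(sum(idx), mix$mu[k], mix$kappa[k])
    }
    out[[sp]] <- x
  }
  out
}

#' Expand detection histories into a photo-burst record table
#'
#' Each site-by-occasion detection becomes one detection event carrying a
#' diel clock time, expanded into a 3-photo burst (photos 1 s apart, one
#' shared burst id). The occasion index gives the date, the diel draw the
#' clock time, so collapsing the records and rebuilding histories
#' reproduces the input exactly.
#'
#' @param histories named list of `detection_history` objects.
#' @param diel named list of radian samples (one value per event; drawn
#'   from the study mixtures if too short), as from [sim_diel()].
#' @param covs covariate table (provides the site universe).
#' @param config the [study_config()].
#' @param start_date first occasion date (default `"2022-12-01"`).
#' @return data.frame with columns `site_id`, `species`, `datetime`
#'   (ISO-8601), `count`, `burst_id`.
#' @export
emit_records <- function(histories, diel, covs, config,
                         start_date = "2022-12-01") {
  start <- as.Date(start_date)
  rows <- list()
  for (sp in names(histories)) {
    y <- histories[[sp]]$y
    hits <- which(y == 1, arr.ind = TRUE)
    times <- diel[[sp]]
    if (nrow(hits) > 0 && length(times) < nrow(hits)) {
      extra <- sim_diel(config, stats::setNames(nrow(hits) - length(times), sp))[[sp]]
      times <- c(times, extra)
    }
    if (nrow(hits) == 0) next
    ord <- order(hits[, 1], hits[, 2])
    hits <- hits[ord, , drop = FALSE]
    secs <- round(times[seq_len(nrow(hits))] / (2 * pi) * 86400) %% 86400
    for (e in seq_len(nrow(hits))) {
      site <- rownames(y)[hits[e, 1]]
      day <- start + (hits[e, 2] - 1)
      t0 <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC") + secs[e]
      # keep the 3-photo burst inside the occasion's date
      t0 <- min(t0, as.POSIXct(paste(day, "23:59:57"), tz = "UTC"))
      bid <- sprintf("%s_%s_%04d", site, sp, e)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = site, species = sp,
        datetime = format(t0 + 0:2, "%Y-%m-%dT%H:%M:%S"),
        count = 1L, burst_id = bid)
    }
  }
  if (length(rows) == 0)
    return(data.frame(site_id = character(), species = character(),
                      datetime = character(), count = integer(),
                      burst_id = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic camera-trap study
#'
#' Orchestrates the generator end to end: covariates, detection histories
#' with ground truth, diel samples sized to the realized detection events
#' (plus human and livestock activity samples), and the expanded photo-burst
#' record table.
#'
#' @param config a [study_config()].
#' @param n_diel_human events to draw for the human and livestock diel
#'   samples (default 500 each).
#' @return an object of class `"cam_study"`: list with `config`,
#'   `covariates`, `histories`, `truth`, `diel`, `records`, `effort`.
#' @export
sim_study <- function(config = study_config(), n_diel_human = 500) {
  covs <- sim_covariates(config)
  sim <- sim_histories(config, covs)
  n_events <- vapply(sim$histories, function(h) sum(h$y == 1, na.rm = TRUE),
                     numeric(1))
  extra <- intersect(c("human", "livestock"), names(config$diel_mixtures))
  n_all <- c(n_events, stats::setNames(rep(n_diel_human, length(extra)), extra))
  diel <- sim_diel(config, n_all)
  records <- emit_records(sim$histories, diel, covs, config)
  effort <- data.frame(site_id = covs$site,
                       start = as.Date("2022-12-01"),
                       end = as.Date("2022-12-01") + config$n_occasions - 1)
  structure(list(config = config, covariates = covs,
                 histories = sim$histories, truth = sim$truth,
                 diel = diel, records = records, effort = effort),
            class = "cam_study")
}

#' @export
print.cam_study <- function(x, ...) {
  cat("Synthetic camera-trap study:", x$config$n_sites, "sites x",
      x$config$n_occasions, "occasions, seed", x$config$seed, "\n")
  ev <- vapply(x$histories, function(h) sum(h$y == 1, na.rm = TRUE), numeric(1))
  naive <- vapply(x$histories, function(h) mean(rowSums(h$y, na.rm = TRUE) > 0),
                  numeric(1))
  print(data.frame(events = ev, naive_occupancy = round(naive, 3)))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Writes `records.csv`, `covariates.csv`, `effort.csv`, `truth.json` and
#' `config.yaml` (seed included) to a directory.
#'
#' @param study a [sim_study()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory path.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "cam_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$records, file.path(dir, "records.csv"), row.names = FALSE)
  utils::write.csv(study$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  utils::write.csv(study$effort, file.path(dir, "effort.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- study$truth
    truth$psi <- as.data.frame(truth$psi); truth$p <- as.data.frame(truth$p)
    truth$z <- as.data.frame(truth$z)
    truth$diel_overlap <- as.data.frame(truth$diel_overlap)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- unclass(study$config)
    cfg$occupancy_coefs <- lapply(cfg$occupancy_coefs, as.list)
    cfg$detection_coefs <- lapply(cfg$detection_coefs, as.list)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
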