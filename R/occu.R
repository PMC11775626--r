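#' Likelihood of one site's detection history
#'
#' Closed-form single-season occupancy likelihood for one site:
#' `L = psi * prod_j p_j^y_j (1 - p_j)^(1 - y_j) + (1 - psi) * I(all y_j = 0)`,
#' where the product runs over the observed (unmasked) occasions. Masked
#' occasions are encoded as `NA` in `y` and excluded.
#'
#' @param y binary detection vector for one site (0/1, `NA` = camera inactive).
#' @param psi space-use (occupancy) probability for the site, in (0, 1).
#' @param p detection probability, scalar or one value per occasion, in (0, 1).
#' @return the likelihood contribution (a probability).
#' @examples
#' site_likelihood(c(0, 0), 0.5, 0.5)  # 0.5 * 0.25 + 0.5 = 0.625
#' @export
site_likelihood <- function(y, psi, p) {
  p <- rep_len(p, length(y))
  obs <- !is.na(y)
  y <- y[obs]; p <- p[obs]
  cond <- prod(p^y * (1 - p)^(1 - y))
  psi * cond + (1 - psi) * as.numeric(all(y == 0))
}

## ---- internal design handling ------------------------------------------

## z-score numeric columns, remembering centre/scale for prediction
standardize_covs <- function(data, center = NULL, scale = NULL) {
  if (is.null(data)) return(list(data = NULL, center = NULL, scale = NULL))
  num <- vapply(data, is.numeric, logical(1))
  if (is.null(center)) {
    center <- vapply(data[num], mean, numeric(1))
    scale <- vapply(data[num], stats::sd, numeric(1))
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  for (nm in names(center)) data[[nm]] <- (data[[nm]] - center[nm]) / scale[nm]
  list(data = data, center = center, scale = scale)
}

## detection matrix + per-site sufficient statistics
.history_matrix <- function(history) {
  y <- if (inherits(history, "detection_history")) history$y else as.matrix(history)
  if (!all(y[!is.na(y)] %in% c(0, 1))) stop("detection history must be binary (0/1/NA)")
  y
}

## ---- maximum likelihood -------------------------------------------------

.occu_negll <- function(par, Xpsi, Xp, d, J, detected) {
  kp <- ncol(Xpsi)
  beta <- par[seq_len(kp)]; alpha <- par[-seq_len(kp)]
  eta_psi <- drop(Xpsi %*% beta)
  eta_p <- drop(Xp %*% alpha)
  psi <- stats::plogis(eta_psi)
  # log conditional likelihood given occupied, on log scale
  lcond <- d * stats::plogis(eta_p, log.p = TRUE) +
    (J - d) * stats::plogis(-eta_p, log.p = TRUE)
  ll <- ifelse(detected,
               log(psi) + lcond,
               log(psi * exp(lcond) + (1 - psi)))
  -sum(ll)
}

## ---- MCMC sampler -------------------------------------------------------

## Metropolis-within-Gibbs: exact full conditional for z, adaptive
## single-coordinate random-walk Metropolis for the logit-scale coefficients.
## p is site-level (constant over occasions), so (d_i, J_i) are sufficient.
.occu_chain <- function(Xpsi, Xp, d, J, detected, prior_mean, prior_sd,
                        adapt, burnin, iter, seed, monitor_sites = TRUE) {
  set.seed(seed)
  n <- nrow(Xpsi); kp <- ncol(Xpsi); kd <- ncol(Xp)
  beta <- rep(0, kp); alpha <- rep(0, kd)
  ls_b <- rep(log(0.5), kp); ls_a <- rep(log(0.5), kd)  # log proposal sd
  acc_b <- integer(kp); acc_a <- integer(kd)
  eta_psi <- drop(Xpsi %*% beta)
  eta_p <- drop(Xp %*% alpha)
  total <- adapt + burnin + iter
  keep_from <- adapt + burnin
  draws <- matrix(NA_real_, iter, kp + kd + 2)
  z <- as.numeric(detected)
  pm <- rep_len(prior_mean, kp + kd); psd <- rep_len(prior_sd, kp + kd)

  log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(pmin(x, 35))))

  for (s in seq_len(total)) {
    ## z | rest: exact full conditional,
    ## psi (1-p)^J / (psi (1-p)^J + 1-psi) = plogis(logit(psi) + J log(1-p))
    lq <- J * stats::plogis(-eta_p, log.p = TRUE)
    pz <- stats::plogis(eta_psi + lq)
    z <- ifelse(detected, 1, stats::rbinom(n, 1, pz))

    ## beta | z : Bernoulli(z; logit = Xpsi beta)
    ll_b <- sum(z * eta_psi) - sum(log1pexp(eta_psi))
    for (k in seq_len(kp)) {
      prop <- stats::rnorm(1, beta[k], exp(ls_b[k]))
      eta_new <- eta_psi + Xpsi[, k] * (prop - beta[k])
      ll_new <- sum(z * eta_new) - sum(log1pexp(eta_new))
      lr <- ll_new - ll_b +
        stats::dnorm(prop, pm[k], psd[k], log = TRUE) -
        stats::dnorm(beta[k], pm[k], psd[k], log = TRUE)
      if (log(stats::runif(1)) < lr) {
        beta[k] <- prop; eta_psi <- eta_new; ll_b <- ll_new
        acc_b[k] <- acc_b[k] + 1L
      }
    }

    ## alpha | z : Binomial(d_i; J_i, p_i) over occupied sites
    occ <- z == 1
    dz <- d[occ]; Jz <- J[occ]
    if (kd > 0) {
      ep_occ <- eta_p[occ]
      ll_a <- sum(dz * ep_occ) - sum(Jz * log1pexp(ep_occ))
      for (k in seq_len(kd)) {
        prop <- stats::rnorm(1, alpha[k], exp(ls_a[k]))
        eta_new <- eta_p + Xp[, k] * (prop - alpha[k])
        en_occ <- eta_new[occ]
        ll_new <- sum(dz * en_occ) - sum(Jz * log1pexp(en_occ))
        j <- kp + k
        lr <- ll_new - ll_a +
          stats::dnorm(prop, pm[j], psd[j], log = TRUE) -
          stats::dnorm(alpha[k], pm[j], psd[j], log = TRUE)
        if (log(stats::runif(1)) < lr) {
          alpha[k] <- prop; eta_p <- eta_new; ll_a <- ll_new
          acc_a[k] <- acc_a[k] + 1L
        }
      }
    }

    ## adaptive phase: tune proposal scales toward 0.3-0.45 acceptance
    if (s <= adapt && s %% 50 == 0) {
      rate_b <- acc_b / 50; rate_a <- acc_a / 50
      ls_b <- ls_b + ifelse(rate_b > 0.45, 0.3, ifelse(rate_b < 0.3, -0.3, 0))
      ls_a <- ls_a + ifelse(rate_a > 0.45, 0.3, ifelse(rate_a < 0.3, -0.3, 0))
      acc_b[] <- 0L; acc_a[] <- 0L
    }

    if (s > keep_from) {
      i <- s - keep_from
      draws[i, seq_len(kp)] <- beta
      draws[i, kp + seq_len(kd)] <- alpha
      draws[i, kp + kd + 1] <- mean(stats::plogis(eta_psi))
      draws[i, kp + kd + 2] <- mean(stats::plogis(eta_p))
    }
  }
  draws
}

#' Fit a single-season occupancy (space-use) model
#'
#' Fits the standard hierarchical detection/non-detection model
#' `z_i ~ Bernoulli(psi_i)`, `y_ij | z_i ~ Bernoulli(z_i * p_i)` with
#' logit-linear covariates on space use (`psi`) and detection (`p`), either by
#' maximum likelihood (`method = "mle"`) or by a built-in adaptive
#' Metropolis-within-Gibbs sampler (`method = "mcmc"`). The latent states are
#' drawn from their exact full conditionals; coefficients use
#' single-coordinate random-walk Metropolis with proposal scales tuned during
#' the adaptation phase (target acceptance 0.3-0.45). Detection covariates
#' are site-level, so `p` is constant across occasions within a site.
#'
#' Covariates are z-scored internally (centre/scale stored for prediction);
#' priors are independent normals on all logit-scale coefficients.
#'
#' @param history binary site-by-occasion matrix (`NA` = inactive
#'   camera-occasion) or a `detection_history` object.
#' @param psi,det right-hand-side formulas for space use and detection, e.g.
#'   `psi = ~ forest + humans`, `det = ~ dist_road`. Intercept-only (`~ 1`)
#'   needs no covariate data.
#' @param data data.frame of site covariates, one row per site in `history`
#'   order.
#' @param method `"mcmc"` (default) or `"mle"`.
#' @param chains,adapt,burnin,iter MCMC run settings; defaults 3 chains, 1000
#'   adaptations, 1000 burn-in, 10000 retained iterations per chain, no
#'   thinning.
#' @param priors list with `mean` and `sd` of the independent normal priors
#'   on logit-scale coefficients (default mean 0, sd 2).
#' @param seed integer seed; chain `c` uses `seed + c - 1`. Required for
#'   reproducible MCMC.
#' @param standardize z-score numeric covariates before fitting (default
#'   `TRUE`).
#' @param level credible/confidence level used by `summary` (default 0.95).
#' @param rhat_threshold convergence threshold; any monitored parameter with
#'   split-chain Rhat above it triggers a warning (default 1.1).
#' @param p_fixed optional fixed detection probability (e.g. `p_fixed = 1`
#'   turns the MLE into the naive-occupancy estimator); MLE only.
#' @return an object of class `"occu"` with methods `print`, `summary`,
#'   `coef`, `vcov`, `predict`, `simulate`, `logLik` and `plot`.
#' @seealso [summary.occu()], [predict.occu()], [site_likelihood()]
#' @examples
#' y <- matrix(rbinom(50 * 5, 1, 0.3), 50, 5)
#' fit <- occu(y, method = "mle")
#' coef(fit)
#' @export
occu <- function(history, psi = ~1, det = ~1, data = NULL,
                 method = c("mcmc", "mle"),
                 chains = 3, adapt = 1000, burnin = 1000, iter = 10000,
                 priors = list(mean = 0, sd = 2), seed = NULL,
                 standardize = TRUE, level = 0.95, rhat_threshold = 1.1,
                 p_fixed = NULL) {
  method <- match.arg(method)
  cl <- match.call()
  y <- .history_matrix(history)
  n <- nrow(y)
  if (n < 1) stop("history needs at least one site")
  if (is.null(data)) data <- data.frame(row.names = seq_len(n))
  if (nrow(data) != n) stop("covariate rows (", nrow(data),
                            ") do not match history sites (", n, ")")
  std <- if (standardize) standardize_covs(data) else list(data = data, center = NULL, scale = NULL)
  Xpsi <- stats::model.matrix(psi, std$data)
  Xp <- stats::model.matrix(det, std$data)
  if (nrow(Xpsi) != n || nrow(Xp) != n)
    stop("design rows do not match history sites (missing covariate values?)")
  d <- rowSums(y == 1, na.rm = TRUE)
  J <- rowSums(!is.na(y))
  detected <- d > 0
  pnames <- c(paste0("psi_", colnames(Xpsi)), paste0("p_", colnames(Xp)))
  if (any(priors$sd <= 0)) stop("prior sds must be positive")

  out <- list(call = cl, method = method, y = y, d = d, J = J,
              Xpsi = Xpsi, Xp = Xp, psi_formula = psi, det_formula = det,
              data = data, center = std$center, scale = std$scale,
              par_names = pnames, level = level, priors = priors)

  if (method == "mle") {
    kp <- ncol(Xpsi)
    if (!is.null(p_fixed)) {
      stopifnot(p_fixed > 0, p_fixed <= 1)
      negll <- function(b) {
        psi_i <- stats::plogis(drop(Xpsi %*% b))
        if (p_fixed == 1) {
          # detection is certain: the site indicator is the Bernoulli outcome
          return(-sum(log(ifelse(detected, psi_i, 1 - psi_i))))
        }
        cond <- p_fixed^d * (1 - p_fixed)^(J - d)
        -sum(log(psi_i * cond + (1 - psi_i) * as.numeric(!detected)))
      }
      opt <- stats::optim(rep(0, kp), negll, method = "BFGS", hessian = TRUE)
      est <- c(opt$par, numeric(0))
      names(est) <- pnames[seq_len(kp)]
      vc <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA, kp, kp))
      out$p_fixed <- p_fixed
    } else {
      k <- ncol(Xpsi) + ncol(Xp)
      opt <- stats::optim(rep(0, k), .occu_negll, Xpsi = Xpsi, Xp = Xp,
                          d = d, J = J, detected = detected,
                          method = "BFGS", hessian = TRUE)
      est <- opt$par
      names(est) <- pnames
      vc <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA, k, k))
    }
    dimnames(vc) <- list(names(est), names(est))
    out$coefficients <- est
    out$vcov <- vc
    out$logLik <- -opt$value
    out$converged <- opt$convergence == 0
    if (!out$converged) warning("optimizer did not report convergence")
  } else {
    if (is.null(seed)) seed <- sample.int(.Machine$integer.max / 2, 1)
    t0 <- proc.time()[3]
    ch <- lapply(seq_len(chains), function(c_i)
      .occu_chain(Xpsi, Xp, d, J, detected,
                  prior_mean = priors$mean, prior_sd = priors$sd,
                  adapt = adapt, burnin = burnin, iter = iter,
                  seed = seed + c_i - 1))
    arr <- array(unlist(ch), dim = c(iter, ncol(Xpsi) + ncol(Xp) + 2, chains),
                 dimnames = list(NULL, c(pnames, "psi", "p"), NULL))
    out$chains <- arr
    out$seed <- seed
    out$settings <- list(chains = chains, adapt = adapt, burnin = burnin, iter = iter)
    out$runtime <- unname(proc.time()[3] - t0)
    pooled <- apply(arr, 2, identity)  # (iter*chains) x params
    out$coefficients <- colMeans(pooled)[seq_along(pnames)]
    rh <- apply(arr, 2, rhat)
    out$rhat <- rh
    out$converged <- all(rh < rhat_threshold, na.rm = TRUE)
    if (!out$converged)
      warning("Rhat > ", rhat_threshold, " for: ",
              paste(names(rh)[rh >= rhat_threshold], collapse = ", "))
  }
  class(out) <- "occu"
  out
}

#' @export
print.occu <- function(x, ...) {
  cat("Single-season occupancy (space-use) model, method =", x$method, "\n")
  cat("Sites:", nrow(x$y), " occasions:", ncol(x$y),
      " naive occupancy:", round(mean(x$d > 0), 3), "\n")
  if (x$method == "mcmc")
    cat(sprintf("MCMC: %d chains x %d iterations (adapt %d, burn-in %d)\n",
                x$settings$chains, x$settings$iter, x$settings$adapt,
                x$settings$burnin))
  cat("\nCoefficients (logit scale):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.occu <- function(object, ...) object$coefficients

#' @export
vcov.occu <- function(object, ...) {
  if (object$method != "mle") stop("vcov is available for MLE fits; use summary() for posteriors")
  object$vcov
}

#' @export
logLik.occu <- function(object, ...) {
  ll <- if (object$method == "mle") object$logLik else {
    kp <- ncol(object$Xpsi)
    b <- object$coefficients[seq_len(kp)]
    a <- object$coefficients[-seq_len(kp)]
    -.occu_negll(c(b, a), object$Xpsi, object$Xp, object$d, object$J,
                 object$d > 0)
  }
  structure(ll, df = length(object$coefficients), class = "logLik")
}

#' Posterior draws of an MCMC fit
#'
#' @param object an `"occu"` fit with `method = "mcmc"`.
#' @param pooled return a single (iterations x parameters) matrix pooling all
#'   chains (`TRUE`, default) or the iterations x parameters x chains array.
#' @return matrix or 3-d array of retained draws (coefficients plus the
#'   derived mean space use `psi` and mean detection `p`).
#' @export
posterior_draws <- function(object, pooled = TRUE) {
  stopifnot(inherits(object, "occu"))
  if (is.null(object$chains)) stop("no chains: fit with method = 'mcmc'")
  if (!pooled) return(object$chains)
  a <- object$chains
  matrix(aperm(a, c(1, 3, 2)), nrow = dim(a)[1] * dim(a)[3],
         dimnames = list(NULL, dimnames(a)[[2]]))
}

#' Summarize an occupancy fit
#'
#' For MCMC fits, returns a posterior summary table with one row per
#' monitored parameter: posterior mean, sd, equal-tailed credible limits
#' (`LCL`, `UCL`), split-chain Gelman-Rubin `Rhat`, autocorrelation-based
#' effective sample size `ESS`, and `overlap0` (1 if the credible interval
#' contains zero, 0 otherwise; a coefficient is "significant" when
#' `overlap0 = 0`). The derived rows `psi` and `p` are the posterior of the
#' across-site means of space use and detection probability. For MLE fits,
#' a Wald summary with normal confidence limits is returned.
#'
#' @param object an `"occu"` fit.
#' @param level credible/confidence level; defaults to the level stored in
#'   the fit (0.95).
#' @param rank_normalized use the rank-normalized split-chain Rhat (default);
#'   `FALSE` gives the classical split-chain variant.
#' @param ... unused.
#' @return a data.frame of class `"summary.occu"`.
#' @export
summary.occu <- function(object, level = NULL, rank_normalized = TRUE, ...) {
  if (is.null(level)) level <- object$level
  alpha <- (1 - level) / 2
  if (object$method == "mle") {
    se <- sqrt(diag(object$vcov))
    z <- stats::qnorm(1 - alpha)
    tab <- data.frame(mean = object$coefficients, sd = se,
                      LCL = object$coefficients - z * se,
                      UCL = object$coefficients + z * se)
  } else {
    pooled <- posterior_draws(object)
    arr <- object$chains
    tab <- data.frame(
      mean = colMeans(pooled),
      sd = apply(pooled, 2, stats::sd),
      LCL = apply(pooled, 2, stats::quantile, probs = alpha),
      UCL = apply(pooled, 2, stats::quantile, probs = 1 - alpha),
      Rhat = apply(arr, 2, rhat, rank_normalized = rank_normalized),
      ESS = apply(arr, 2, ess))
  }
  tab$overlap0 <- as.integer(tab$LCL <= 0 & tab$UCL >= 0)
  attr(tab, "level") <- level
  attr(tab, "method") <- object$method
  class(tab) <- c("summary.occu", "data.frame")
  tab
}

#' @export
print.summary.occu <- function(x, digits = 3, ...) {
  cat(sprintf("%s summary (%d%% intervals); overlap0 = 0 marks coefficients whose interval excludes zero\n",
              if (attr(x, "method") == "mle") "Wald" else "Posterior",
              round(100 * attr(x, "level"))))
  print(round(as.data.frame(x), digits))
  invisible(x)
}

#' Predict space use or detection probability per site
#'
#' Applies the stored covariate standardization to `newdata`, forms the
#' linear predictor per retained draw (MCMC) or at the point estimate (MLE),
#' and inverse-logit transforms.
#'
#' @param object an `"occu"` fit.
#' @param newdata optional data.frame of covariates; default the fitting data.
#' @param type `"psi"` (space use) or `"p"` (detection).
#' @param level credible level for MCMC summaries.
#' @param ... unused.
#' @return data.frame with one row per site: posterior `mean`, `sd`, `LCL`,
#'   `UCL` (MCMC) or the point estimate (MLE).
#' @export
predict.occu <- function(object, newdata = NULL, type = c("psi", "p"),
                         level = NULL, ...) {
  type <- match.arg(type)
  if (is.null(level)) level <- object$level
  alpha <- (1 - level) / 2
  if (is.null(newdata)) newdata <- object$data
  std <- if (!is.null(object$center))
    standardize_covs(newdata, object$center, object$scale)$data else newdata
  form <- if (type == "psi") object$psi_formula else object$det_formula
  X <- stats::model.matrix(form, std)
  kp <- ncol(object$Xpsi)
  idx <- if (type == "psi") seq_len(kp) else kp + seq_len(ncol(object$Xp))
  if (object$method == "mle") {
    est <- stats::plogis(drop(X %*% object$coefficients[idx]))
    return(data.frame(estimate = est))
  }
  draws <- posterior_draws(object)[, idx, drop = FALSE]
  eta <- tcrossprod(X, draws)           # sites x draws
  prob <- stats::plogis(eta)
  data.frame(mean = rowMeans(prob),
             sd = apply(prob, 1, stats::sd),
             LCL = apply(prob, 1, stats::quantile, probs = alpha),
             UCL = apply(prob, 1, stats::quantile, probs = 1 - alpha))
}

#' Simulate detection histories from a fitted model
#'
#' Draws latent occupancy and detections from the fitted data-generating
#' process (at the posterior mean or MLE coefficients), preserving the
#' effort mask of the fitted history.
#'
#' @param object an `"occu"` fit.
#' @param nsim number of replicate histories.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of site x occasion matrices.
#' @export
simulate.occu <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  kp <- ncol(object$Xpsi)
  psi <- stats::plogis(drop(object$Xpsi %*% object$coefficients[seq_len(kp)]))
  p <- stats::plogis(drop(object$Xp %*% object$coefficients[-seq_len(kp)]))
  n <- nrow(object$y); J <- ncol(object$y)
  mask <- is.na(object$y)
  replicate(nsim, {
    z <- stats::rbinom(n, 1, psi)
    y <- matrix(stats::rbinom(n * J, 1, rep(z * p, J)), n, J)
    y[mask] <- NA
    y
  }, simplify = FALSE)
}

#' Caterpillar plot of coefficient intervals
#'
#' @param x an `"occu"` fit.
#' @param ... passed to [summary.occu()].
#' @return invisibly, the summary table plotted.
#' @export
plot.occu <- function(x, ...) {
  s <- summary(x, ...)
  keep <- rownames(s)[grepl("^(psi_|p_)", rownames(s))]
  s <- s[keep, ]
  k <- nrow(s)
  graphics::plot(s$mean, seq_len(k), xlim = range(s$LCL, s$UCL, 0),
                 yaxt = "n", ylab = "", xlab = "coefficient (logit scale)",
                 pch = 16)
  graphics::axis(2, at = seq_len(k), labels = rownames(s), las = 1, cex.axis = 0.8)
  graphics::segments(s$LCL, seq_len(k), s$UCL, seq_len(k))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(s)
}
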