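#' Convert clock times to radian time of day
#'
#' Maps a time of day to the circle: `t = 2 * pi * s / 86400` where `s` is
#' seconds since midnight, so midnight is 0 and noon is `pi`.
#'
#' @param x a `POSIXct`/`POSIXlt` vector, a character vector of `"HH:MM:SS"`
#'   (or `"HH:MM"`) clock times, or a numeric vector of decimal hours.
#' @return numeric vector of radian times in `[0, 2*pi)`.
#' @examples
#' to_radians(c("00:00:00", "12:00:00", "18:00:00"))
#' @export
to_radians <- function(x) {
  if (inherits(x, "POSIXt")) {
    lt <- as.POSIXlt(x)
    s <- lt$hour * 3600 + lt$min * 60 + lt$sec
  } else if (is.character(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)
    s <- vapply(parts, function(p) {
      p <- as.numeric(p)
      if (any(is.na(p))) return(NA_real_)
      sum(p * c(3600, 60, 1)[seq_along(p)])
    }, numeric(1))
  } else if (is.numeric(x)) {
    s <- (x %% 24) * 3600
  } else {
    stop("cannot convert objects of class '", class(x)[1], "' to radian time")
  }
  (2 * pi * s / 86400) %% (2 * pi)
}

## von Mises density, numerically stable for large kappa via scaled Bessel
dvonmises <- function(theta, mu, kappa) {
  exp(kappa * (cos(theta - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Used for smoothed (kernel) bootstrap
#' resampling and for the synthetic diel-activity generator.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0; 0 gives the circular uniform).
#' @return numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nk <- sum(ok)
    if (nk > 0) {
      out[(got + 1):(got + nk)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + nk
    }
  }
  (out + mu) %% (2 * pi)
}

## mean resultant length of a circular sample
resultant_length <- function(x) {
  sqrt(mean(cos(x))^2 + mean(sin(x))^2)
}

#' Maximum-likelihood von Mises concentration
#'
#' Solves `A(kappa) = I1(kappa)/I0(kappa) = Rbar` for the concentration,
#' where `Rbar` is the sample mean resultant length.
#'
#' @param x angles in radians.
#' @param kappa_max cap applied when the sample is (near-)degenerate
#'   (`Rbar` within 1e-8 of 1), with a warning.
#' @return estimated concentration `kappa >= 0`.
#' @export
kappa_ml <- function(x, kappa_max = 1e4) {
  rbar <- resultant_length(x)
  if (rbar >= 1 - 1e-8) {
    warning("all observations (nearly) identical; kappa capped at ", kappa_max)
    return(kappa_max)
  }
  if (rbar < 1e-12) return(0)
  afun <- function(k) besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  # Fisher (1993) starting value, then refine
  k0 <- if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6
        else if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
        else 1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  k0 <- min(max(k0, 1e-8), kappa_max)
  stats::uniroot(function(k) afun(k) - rbar, lower = 1e-10, upper = kappa_max,
                 f.lower = -rbar, tol = 1e-10)$root
}

#' Plug-in kernel concentration for circular KDE
#'
#' Estimates the von Mises concentration by maximum likelihood and converts it
#' to a kernel concentration with the standard plug-in rule
#' `kappa_kernel = (n * kappa^2 * 3 * I2(2*kappa) / (4 * sqrt(pi) * I1(kappa)^2))^(2/5)`,
#' multiplied by `adjust`.
#'
#' @param x angles in radians (n >= 2).
#' @param adjust bandwidth multiplier (> 0); smaller values smooth more.
#' @return kernel concentration (> 0).
#' @export
bandwidth_kappa <- function(x, adjust = 1) {
  stopifnot(length(x) >= 2, adjust > 0)
  n <- length(x)
  k <- kappa_ml(x)
  if (k < 1e-8) k <- 1e-8
  # scaled Bessels: I2(2k)/I1(k)^2 = i2s(2k) * e^{2k} / (i1s(k) e^{k})^2
  ratio <- besselI(2 * k, 2, expon.scaled = TRUE) / besselI(k, 1, expon.scaled = TRUE)^2
  adjust * (n * k^2 * 3 * ratio / (4 * sqrt(pi)))^(2 / 5)
}

#' Circular kernel density estimate
#'
#' von Mises kernel density on the circle,
#' `f(t) = (1/n) * sum_i exp(kappa * cos(t - x_i)) / (2 * pi * I0(kappa))`.
#'
#' @param x angles in radians (n >= 1).
#' @param kappa kernel concentration (> 0); if `NULL`, chosen by
#'   [bandwidth_kappa()].
#' @param at evaluation points in radians; default a regular 512-point grid
#'   on `[0, 2*pi)`.
#' @param adjust bandwidth multiplier passed to [bandwidth_kappa()].
#' @return numeric vector of density values at `at`, with the grid in
#'   attribute `"at"` and the concentration in `"kappa"`.
#' @export
circ_density <- function(x, kappa = NULL, at = NULL, adjust = 1) {
  if (length(x) < 1) stop("empty sample: need at least one observation")
  if (is.null(kappa)) kappa <- bandwidth_kappa(x, adjust = adjust)
  stopifnot(kappa > 0)
  if (is.null(at)) at <- seq(0, 2 * pi, length.out = 513)[-513]
  f <- .kde_eval(x, kappa, at)
  attr(f, "at") <- at
  attr(f, "kappa") <- kappa
  f
}

## fast vectorised KDE evaluation: cos(t - x) via a rank-2 product
.kde_eval <- function(x, kappa, at) {
  A <- cbind(cos(at), sin(at))      # m x 2
  B <- rbind(cos(x), sin(x))        # 2 x n
  C <- A %*% B                      # cos(at_j - x_i)
  i0 <- besselI(kappa, 0, expon.scaled = TRUE)
  rowMeans(exp(kappa * (C - 1))) / (2 * pi * i0)
}

#' Coefficient of overlapping between two diel activity samples
#'
#' Estimates the area under the pointwise minimum of the two circular kernel
#' density estimates, the coefficient of overlapping Delta in `[0, 1]`
#' (0 = no overlap, 1 = complete overlap). `Dhat1` integrates
#' `min(f, g)` on a regular grid; `Dhat4` averages density ratios evaluated
#' at the observations,
#' `0.5 * (mean(min(g(x)/f(x), 1)) + mean(min(f(y)/g(y), 1)))`.
#' The `"auto"` rule uses `Dhat1` when the smaller sample has fewer than 50
#' observations and `Dhat4` otherwise.
#'
#' @param x,y radian samples for the two species (both nonempty).
#' @param estimator `"auto"`, `"Dhat1"` or `"Dhat4"`.
#' @param adjust bandwidth multiplier; default 0.8 for `Dhat1`, 1 for `Dhat4`.
#' @param n_grid grid size for `Dhat1` integration.
#' @param kappa optional length-2 vector of fixed kernel concentrations.
#' @return an object of class `"overlap_est"`: list with `dhat`, `estimator`,
#'   `n1`, `n2`, `kappa1`, `kappa2`, `adjust`.
#' @export
overlap_est <- function(x, y, estimator = c("auto", "Dhat1", "Dhat4"),
                        adjust = NULL, n_grid = 512, kappa = NULL) {
  estimator <- match.arg(estimator)
  if (length(x) < 1 || length(y) < 1) stop("empty sample: both samples must be nonempty")
  if (estimator == "auto") estimator <- if (min(length(x), length(y)) < 50) "Dhat1" else "Dhat4"
  if (is.null(adjust)) adjust <- if (estimator == "Dhat1") 0.8 else 1
  k1 <- if (!is.null(kappa)) kappa[1] else bandwidth_kappa(x, adjust = adjust)
  k2 <- if (!is.null(kappa)) kappa[min(2, length(kappa))] else bandwidth_kappa(y, adjust = adjust)
  if (estimator == "Dhat1") {
    grid <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
    f <- .kde_eval(x, k1, grid)
    g <- .kde_eval(y, k2, grid)
    dhat <- mean(pmin(f, g)) * 2 * pi
  } else {
    fx <- .kde_eval(x, k1, x); gx <- .kde_eval(y, k2, x)
    fy <- .kde_eval(x, k1, y); gy <- .kde_eval(y, k2, y)
    dhat <- 0.5 * (mean(pmin(gx / fx, 1)) + mean(pmin(fy / gy, 1)))
  }
  structure(list(dhat = min(max(dhat, 0), 1), estimator = estimator,
                 n1 = length(x), n2 = length(y),
                 kappa1 = k1, kappa2 = k2, adjust = adjust),
            class = "overlap_est")
}

#' @export
print.overlap_est <- function(x, ...) {
  cat(sprintf("Activity overlap %s = %.3f  (n1 = %d, n2 = %d)\n",
              x$estimator, x$dhat, x$n1, x$n2))
  invisible(x)
}

## one smoothed (kernel) or raw resample of a diel sample
.resample_diel <- function(x, kappa, smoothed) {
  idx <- sample.int(length(x), replace = TRUE)
  if (!smoothed) return(x[idx])
  (x[idx] + rvonmises(length(x), 0, kappa)) %% (2 * pi)
}

#' Bootstrap confidence interval for an overlap coefficient
#'
#' Resamples each group independently (smoothed resampling from the fitted
#' kernel density by default, raw resampling optionally), recomputes the
#' overlap coefficient, and forms a confidence interval. `norm0` is
#' `dhat +/- z * sd(boot)` centred at the original estimate; `basic0` is the
#' basic bootstrap interval centred the same way; `percentile` uses the
#' bootstrap quantiles. Bounds are clamped to `[0, 1]`.
#'
#' @inheritParams overlap_est
#' @param n_boot number of bootstrap resamples (default 999).
#' @param method `"norm0"`, `"basic0"` or `"percentile"`.
#' @param conf confidence level.
#' @param smoothed use smoothed (kernel) resampling.
#' @return an object of class `"overlap_ci"`: list with `dhat`, `lower`,
#'   `upper`, `n_boot`, `method`, `conf`, `boot` (the resampled coefficients).
#' @export
overlap_ci <- function(x, y, n_boot = 999, method = c("norm0", "basic0", "percentile"),
                       estimator = c("auto", "Dhat1", "Dhat4"), adjust = NULL,
                       conf = 0.95, smoothed = TRUE) {
  method <- match.arg(method)
  est <- overlap_est(x, y, estimator = estimator, adjust = adjust)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    xb <- .resample_diel(x, est$kappa1, smoothed)
    yb <- .resample_diel(y, est$kappa2, smoothed)
    boot[b] <- overlap_est(xb, yb, estimator = est$estimator, adjust = est$adjust)$dhat
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  bounds <- switch(method,
    norm0 = est$dhat + c(-1, 1) * z * stats::sd(boot),
    basic0 = {
      q <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
      est$dhat - (q - mean(boot))[2:1]
    },
    percentile = stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE))
  structure(list(dhat = est$dhat, lower = max(bounds[1], 0), upper = min(bounds[2], 1),
                 n_boot = n_boot, method = method, conf = conf,
                 estimator = est$estimator, boot = boot),
            class = "overlap_ci")
}

#' @export
print.overlap_ci <- function(x, ...) {
  cat(sprintf("%s = %.3f, %d%% %sCI = %.3f-%.3f (%d bootstraps)\n",
              x$estimator, x$dhat, round(100 * x$conf), x$method,
              x$lower, x$upper, x$n_boot))
  invisible(x)
}

#' Randomization test of activity overlap
#'
#' Tests whether two diel samples could share one activity pattern: a kernel
#' density is fitted to the pooled sample, null pairs of sizes `n1`, `n2` are
#' drawn from it, and the observed overlap coefficient is compared with the
#' null distribution. Small overlap is evidence against a shared pattern, so
#' `p = (1 + #\{null dhat <= observed dhat\}) / (n_null + 1)`.
#'
#' @inheritParams overlap_est
#' @param n_null number of null resamples (default 999).
#' @return a list of class `"overlap_test"` with `p.value`, `dhat`,
#'   `null` (the null coefficients), `n_null`, `estimator`.
#' @export
overlap_test <- function(x, y, n_null = 999, estimator = c("auto", "Dhat1", "Dhat4"),
                         adjust = NULL) {
  obs <- overlap_est(x, y, estimator = estimator, adjust = adjust)
  pooled <- c(x, y)
  k_pool <- bandwidth_kappa(pooled, adjust = obs$adjust)
  null <- numeric(n_null)
  n1 <- length(x); n2 <- length(y)
  for (b in seq_len(n_null)) {
    sim <- (pooled[sample.int(n1 + n2, n1 + n2, replace = TRUE)] +
              rvonmises(n1 + n2, 0, k_pool)) %% (2 * pi)
    null[b] <- overlap_est(sim[seq_len(n1)], sim[n1 + seq_len(n2)],
                           estimator = obs$estimator, adjust = obs$adjust)$dhat
  }
  p <- (1 + sum(null <= obs$dhat)) / (n_null + 1)
  structure(list(p.value = p, dhat = obs$dhat, null = null, n_null = n_null,
                 estimator = obs$estimator),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Randomization test of activity overlap: %s = %.3f, p = %.4g (%d null draws)\n",
              x$estimator, x$dhat, x$p.value, x$n_null))
  invisible(x)
}

#' Pairwise overlap matrix for several species
#'
#' @param samples named list of radian samples, one per species.
#' @param ... passed to [overlap_est()].
#' @return symmetric numeric matrix of overlap coefficients with unit
#'   diagonal.
#' @export
overlap_matrix <- function(samples, ...) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  k <- length(samples)
  m <- diag(1, k)
  dimnames(m) <- list(names(samples), names(samples))
  if (k < 2) return(m)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- overlap_est(samples[[i]], samples[[j]], ...)$dhat
  }
  m
}

#' Paired diel activity density plot
#'
#' Plots the two circular kernel densities on a 0-24 h axis and shades the
#' area under their pointwise minimum (the overlap coefficient).
#'
#' @inheritParams overlap_est
#' @param labels character length-2 legend labels.
#' @param main plot title.
#' @return invisibly, a data.frame of the plotted densities.
#' @export
plot_overlap <- function(x, y, labels = c("species 1", "species 2"),
                         adjust = NULL, main = NULL) {
  if (is.null(adjust)) adjust <- 0.8
  grid <- seq(0, 2 * pi, length.out = 257)
  f <- .kde_eval(x, bandwidth_kappa(x, adjust), grid)
  g <- .kde_eval(y, bandwidth_kappa(y, adjust), grid)
  h <- grid * 24 / (2 * pi)
  graphics::plot(h, f, type = "n", ylim = c(0, max(f, g) * 1.05),
                 xlab = "time of day (h)", ylab = "density", xaxt = "n",
                 main = main)
  graphics::axis(1, at = seq(0, 24, 6))
  graphics::polygon(c(h, rev(h)), c(pmin(f, g), rep(0, length(h))),
                    col = "grey85", border = NA)
  graphics::lines(h, f, lty = 1)
  graphics::lines(h, g, lty = 2, col = "grey40")
  graphics::legend("topright", legend = labels, lty = 1:2,
                   col = c("black", "grey40"), bty = "n")
  invisible(data.frame(hour = h, d1 = f, d2 = g))
}
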