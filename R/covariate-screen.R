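#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` comes from the least-squares
#' regression of column `k` on all other columns (with intercept).
#'
#' @param X numeric data.frame or matrix of candidate covariates.
#' @return named numeric vector of VIFs (>= 1; `Inf` for an exact linear
#'   combination).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  out <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (k in seq_len(ncol(X))) {
    yk <- X[, k]
    Zk <- cbind(1, X[, -k, drop = FALSE])
    fit <- stats::lm.fit(Zk, yk)
    rss <- sum(fit$residuals^2)
    tss <- sum((yk - mean(yk))^2)
    r2 <- if (tss == 0) 0 else 1 - rss / tss
    out[k] <- if (r2 >= 1 - 1e-14) Inf else 1 / (1 - r2)
  }
  out
}

#' Collinearity screen: correlation cutoff then VIF removal
#'
#' Two-phase stepwise screen. Phase 1: while any retained pair has
#' `|r| > r_threshold` (Pearson, on standardized columns), the worst pair is
#' located and its non-kept member with the larger VIF is dropped. Phase 2:
#' while the largest VIF among non-kept retained columns exceeds
#' `vif_threshold`, that column is dropped. Columns named in `keep` are never
#' removed ("ecologically important" preference); if the keep set itself
#' violates a threshold this is reported with a warning but honoured.
#'
#' @param X numeric data.frame or matrix (>= 2 columns, none constant).
#' @param r_threshold pairwise correlation cutoff (default 0.7).
#' @param vif_threshold VIF cutoff (default 5).
#' @param keep character vector of columns never to drop.
#' @return an object of class `"covariate_screen"`: list with `retained`,
#'   `dropped` (data.frame: variable, reason, value), `correlation` (input
#'   correlation matrix), `vif` (final VIFs of the retained set), and
#'   `keep_violations`.
#' @export
screen_covariates <- function(X, r_threshold = 0.7, vif_threshold = 5,
                              keep = character()) {
  X <- as.data.frame(X)
  num <- vapply(X, is.numeric, logical(1))
  X <- X[num]
  if (ncol(X) < 2) stop("need at least two numeric columns")
  const <- vapply(X, function(v) stats::sd(v) == 0, logical(1))
  if (any(const)) stop("constant column(s): ", paste(names(X)[const], collapse = ", "))
  bad_keep <- setdiff(keep, names(X))
  if (length(bad_keep)) stop("keep column(s) not in the table: ",
                             paste(bad_keep, collapse = ", "))
  cmat <- stats::cor(X)
  retained <- names(X)
  dropped <- data.frame(variable = character(), reason = character(),
                        value = numeric())
  drop_one <- function(v, reason, value) {
    retained <<- setdiff(retained, v)
    dropped <<- rbind(dropped, data.frame(variable = v, reason = reason,
                                          value = value))
  }

  repeat {   # phase 1: pairwise correlation
    cc <- abs(stats::cor(X[retained]))
    diag(cc) <- 0
    if (max(cc) <= r_threshold) break
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    pair <- retained[ij]
    cand <- setdiff(pair, keep)
    if (length(cand) == 0) break  # both kept: reported below
    v <- vif(X[retained])
    worst <- cand[which.max(v[cand])]
    drop_one(worst, sprintf("|r| = %.3f with %s", max(cc),
                            setdiff(pair, worst)[1]), max(cc))
  }
  repeat {   # phase 2: VIF
    v <- vif(X[retained])
    cand <- setdiff(retained, keep)
    if (length(cand) == 0 || max(v[cand]) <= vif_threshold) break
    worst <- cand[which.max(v[cand])]
    drop_one(worst, sprintf("VIF = %.3g", v[worst]), v[worst])
  }

  final_vif <- vif(X[retained])
  cc <- abs(stats::cor(X[retained])); diag(cc) <- 0
  viol <- character()
  if (length(keep)) {
    if (any(cc[keep, , drop = FALSE] > r_threshold))
      viol <- c(viol, "kept column(s) in a pair with |r| above the threshold")
    if (any(final_vif[intersect(keep, names(final_vif))] > vif_threshold))
      viol <- c(viol, "kept column(s) with VIF above the threshold")
    if (length(viol)) warning("keep set violates screening thresholds: ",
                              paste(viol, collapse = "; "))
  }
  structure(list(retained = retained, dropped = dropped, correlation = cmat,
                 vif = final_vif, r_threshold = r_threshold,
                 vif_threshold = vif_threshold, keep = keep,
                 keep_violations = viol),
            class = "covariate_screen")
}

#' @export
print.covariate_screen <- function(x, ...) {
  cat(sprintf("Collinearity screen (|r| > %g, VIF > %g)\n",
              x$r_threshold, x$vif_threshold))
  cat("Retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("Dropped:\n")
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("  %s (%s)\n", x$dropped$variable[i], x$dropped$reason[i]))
  } else cat("Dropped: none\n")
  if (length(x$keep_violations))
    cat("Note:", paste(x$keep_violations, collapse = "; "), "\n")
  invisible(x)
}
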