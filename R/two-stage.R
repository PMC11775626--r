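#' Significance flags from a posterior summary
#'
#' A covariate is flagged significant when its credible interval excludes
#' zero (`overlap0 = 0`). An interval with a bound exactly at zero contains
#' zero (closed-interval convention) and is therefore not significant.
#'
#' @param summary a [summary.occu()] table or any data.frame with `LCL` and
#'   `UCL` columns.
#' @return named logical vector, one flag per row.
#' @export
is_significant <- function(summary) {
  stats::setNames(!(summary$LCL <= 0 & summary$UCL >= 0), rownames(summary))
}

#' Inverse-distance-weighted interpolation of site values
#'
#' `value(s) = sum_i d_i^-power * v_i / sum_i d_i^-power` over the sites;
#' a query point coinciding with a site returns that site's value exactly.
#' Being a weighted average, the output is bounded by the range of the site
#' values.
#'
#' @param coords numeric matrix or data.frame of site coordinates (x, y).
#' @param values numeric vector of site values (e.g. space-use
#'   probabilities).
#' @param grid either a 2-column matrix of query points, or `NULL` to build
#'   a regular grid of cell centres covering the sites.
#' @param cell grid cell size (same units as `coords`; default 250).
#' @param power IDW power parameter (default 2).
#' @param pad margin added around the site bounding box when building the
#'   grid (default one cell).
#' @return an object of class `"idw_grid"`: list with `grid` (data.frame
#'   `x`, `y`, `value`), `cell`, `power`, `nx`, `ny`, `origin`; or, when
#'   `grid` was a matrix of query points, a numeric vector of interpolated
#'   values.
#' @export
idw <- function(coords, values, grid = NULL, cell = 250, power = 2,
                pad = NULL) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  storage.mode(coords) <- "double"
  if (nrow(coords) < 1) stop("need at least one site")
  stopifnot(length(values) == nrow(coords), power > 0)
  as_grid <- is.null(grid)
  if (as_grid) {
    if (is.null(pad)) pad <- cell
    xr <- range(coords[, 1]) + c(-pad, pad)
    yr <- range(coords[, 2]) + c(-pad, pad)
    xs <- seq(xr[1] + cell / 2, xr[2], by = cell)
    ys <- seq(yr[1] + cell / 2, yr[2], by = cell)
    q <- as.matrix(expand.grid(x = xs, y = ys))
  } else {
    q <- as.matrix(grid)[, 1:2, drop = FALSE]
  }
  d2 <- outer(q[, 1], coords[, 1], "-")^2 + outer(q[, 2], coords[, 2], "-")^2
  vals <- numeric(nrow(q))
  zero <- d2 < .Machine$double.eps
  hit <- rowSums(zero) > 0
  if (any(hit)) vals[hit] <- values[apply(zero[hit, , drop = FALSE], 1, which.max)]
  if (any(!hit)) {
    w <- d2[!hit, , drop = FALSE]^(-power / 2)
    vals[!hit] <- drop(w %*% values) / rowSums(w)
  }
  if (!as_grid) return(vals)
  structure(list(grid = data.frame(x = q[, 1], y = q[, 2], value = vals),
                 cell = cell, power = power,
                 nx = length(xs), ny = length(ys),
                 origin = c(xr[1], yr[1])),
            class = "idw_grid")
}

#' @export
print.idw_grid <- function(x, ...) {
  cat(sprintf("IDW grid: %d x %d cells of %g (power %g), value range %.3f-%.3f\n",
              x$nx, x$ny, x$cell, x$power,
              min(x$grid$value), max(x$grid$value)))
  invisible(x)
}

#' Write an IDW grid as an ASCII raster
#'
#' Simple ESRI-style ASCII grid (`ncols/nrows/xllcorner/yllcorner/cellsize`
#' header, rows from north to south).
#'
#' @param x an `"idw_grid"`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_asc <- function(x, path) {
  stopifnot(inherits(x, "idw_grid"))
  m <- matrix(x$grid$value, x$nx, x$ny)  # column j = y level j
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", x$nx), paste("nrows", x$ny),
               paste("xllcorner", x$origin[1]), paste("yllcorner", x$origin[2]),
               paste("cellsize", x$cell), "NODATA_value -9999"), con)
  for (j in rev(seq_len(x$ny)))
    writeLines(paste(format(m[, j], trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' Stage 1: prey space-use models with constant detection
#'
#' Fits one occupancy model per prey species with an intercept-only
#' detection model (constant detection probability across sites) and the
#' given space-use covariates, plus a competing-species presence covariate:
#' the naive detection indicator (any detection) of each other prey species,
#' summed. Species with zero detections are skipped with a report entry.
#'
#' @param histories named list of `detection_history` objects (prey only).
#' @param covariates data.frame of screened site covariates.
#' @param psi_formula right-hand-side formula for prey space use; terms must
#'   name columns of `covariates` (after adding `competitors`).
#' @param competitors add the competing-species presence covariate
#'   (default `TRUE`).
#' @param ... passed to [occu()] (MCMC settings, seed, priors).
#' @return list of class `"prey_stage"`: `fits` (named list of `occu`
#'   objects), `psi_sites` (sites x species matrix of posterior-mean space
#'   use), `table1` (per-species detection and space-use summary rows),
#'   `skipped`.
#' @export
run_prey_stage <- function(histories, covariates,
                           psi_formula = ~ humans + livestock + dist_road +
                             dist_settlement + canopy + forest + competitors,
                           competitors = TRUE, ...) {
  species <- names(histories)
  naive <- vapply(histories, function(h)
    as.numeric(rowSums(h$y == 1, na.rm = TRUE) > 0), numeric(nrow(covariates)))
  fits <- list(); skipped <- character()
  psi_sites <- matrix(NA_real_, nrow(covariates), length(species),
                      dimnames = list(covariates$site, species))
  rows <- list()
  for (sp in species) {
    h <- histories[[sp]]
    if (sum(h$y == 1, na.rm = TRUE) == 0) {
      skipped <- c(skipped, sp)
      next
    }
    covs <- covariates
    if (competitors)
      covs$competitors <- rowSums(naive[, setdiff(species, sp), drop = FALSE])
    fit <- occu(h, psi = psi_formula, det = ~1, data = covs, ...)
    fits[[sp]] <- fit
    psi_sites[, sp] <- predict(fit, type = "psi")$mean
    s <- summary(fit)
    rows[[sp]] <- cbind(species = sp,
                        parameter = c("p", "psi"),
                        as.data.frame(s[c("p", "psi"), ]))
  }
  table1 <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL
  structure(list(fits = fits, psi_sites = psi_sites, table1 = table1,
                 skipped = skipped),
            class = "prey_stage")
}

#' Stage 2: predator space-use model with prey space use as covariates
#'
#' Joins the per-site posterior-mean prey space-use columns
#' (`psi_<species>`) onto the covariate table — standardized like any other
#' covariate by default — and fits the predator model with covariates on
#' both space use and detection.
#'
#' @param history the predator `detection_history`.
#' @param covariates screened covariate table.
#' @param prey_psi sites x species matrix from [run_prey_stage()].
#' @param psi_formula space-use formula; `psi_<species>` terms refer to prey
#'   columns.
#' @param det_formula detection formula (landscape features).
#' @param prey_fits optional named list of stage-1 `occu` fits; required when
#'   `propagate = TRUE`.
#' @param propagate propagate stage-1 posterior uncertainty: instead of the
#'   posterior-mean prey psi, the predator model is refitted over
#'   `n_stage1_draws` random joint posterior draws of the per-site prey psi
#'   and the single-chain runs are pooled (off by default — the posterior
#'   means are used as fixed covariates).
#' @param n_stage1_draws number of stage-1 draws when propagating.
#' @param ... passed to [occu()].
#' @return the fitted `occu` object, with the assembled covariate table in
#'   `$data`; when propagating, the chains dimension indexes stage-1 draws.
#' @export
run_tiger_stage <- function(history, covariates, prey_psi,
                            psi_formula = ~ forest + humans + livestock +
                              psi_blue_bull + psi_gaur + psi_wild_pig,
                            det_formula = ~ dist_road + dist_water,
                            prey_fits = NULL, propagate = FALSE,
                            n_stage1_draws = 10, ...) {
  need <- all.vars(psi_formula)
  check_cols <- function(covs) {
    miss <- setdiff(need[startsWith(need, "psi_")], names(covs))
    if (length(miss))
      stop("prey space-use column(s) missing for: ",
           paste(sub("^psi_", "", miss), collapse = ", "))
  }
  if (!propagate) {
    covs <- covariates
    for (sp in colnames(prey_psi)) covs[[paste0("psi_", sp)]] <- prey_psi[, sp]
    check_cols(covs)
    return(occu(history, psi = psi_formula, det = det_formula, data = covs, ...))
  }
  if (is.null(prey_fits)) stop("propagate = TRUE needs the stage-1 `prey_fits`")
  args <- list(...)
  args$chains <- 1
  base_seed <- if (is.null(args$seed)) 1L else args$seed
  fits <- vector("list", n_stage1_draws)
  for (b in seq_len(n_stage1_draws)) {
    covs <- covariates
    for (sp in names(prey_fits)) {
      draws <- posterior_draws(prey_fits[[sp]])
      idx <- ((base_seed + b * 7919) %% nrow(draws)) + 1  # deterministic draw
      kp <- ncol(prey_fits[[sp]]$Xpsi)
      covs[[paste0("psi_", sp)]] <-
        stats::plogis(drop(prey_fits[[sp]]$Xpsi %*% draws[idx, seq_len(kp)]))
    }
    check_cols(covs)
    args$seed <- base_seed + b
    fits[[b]] <- do.call(occu, c(list(history, psi = psi_formula,
                                      det = det_formula, data = covs), args))
  }
  out <- fits[[n_stage1_draws]]
  out$chains <- array(unlist(lapply(fits, `[[`, "chains")),
                      dim = c(dim(fits[[1]]$chains)[1:2], n_stage1_draws),
                      dimnames = dimnames(fits[[1]]$chains))
  out$settings$chains <- n_stage1_draws
  out$stage1_propagated <- TRUE
  out
}

#' Run the full two-stage space-use pipeline
#'
#' Orchestrates the complete spatial analysis of a camera-trap study:
#' collinearity screening of the site covariates, prey space-use fits with
#' constant detection, the predator fit with prey space use as covariates
#' and landscape features on detection, credible-interval significance
#' flags, and IDW projection of predator space use onto a map grid.
#'
#' @param study a `"cam_study"` (from [sim_study()]) or a list with
#'   `histories` (named, predator included), `covariates` (with `site`,
#'   `x`, `y`).
#' @param predator name of the predator history (default `"tiger"`).
#' @param screen_cols covariate columns entering the collinearity screen.
#' @param keep columns never dropped by the screen.
#' @param prey_formula,tiger_psi_formula,tiger_det_formula model formulas;
#'   defaults follow `screen`-surviving columns and the prey psi columns.
#' @param cell,power IDW grid cell size and power.
#' @param seed integer seed for both stages.
#' @param ... passed to [occu()] (chains, adapt, burnin, iter, priors).
#' @return an object of class `"tiger_pipeline"`: `screen`, `prey`
#'   (stage-1 result), `tiger` (stage-2 `occu` fit), `table1`, `table2`,
#'   `significant`, `psi_sites` (per-site predator space use), `grid`
#'   (`idw_grid`), `report` (seeds, settings, convergence).
#' @export
tiger_pipeline <- function(study, predator = "tiger",
                           screen_cols = c("dist_water", "dist_road",
                                           "dist_settlement", "canopy",
                                           "forest", "humans", "livestock"),
                           keep = c("forest", "humans", "livestock"),
                           prey_formula = NULL,
                           tiger_psi_formula = NULL,
                           tiger_det_formula = ~ dist_road + dist_water,
                           cell = 250, power = 2, seed = 1, ...) {
  histories <- study$histories
  covariates <- study$covariates
  if (is.null(histories[[predator]])) stop("no history for predator '", predator, "'")
  scr <- screen_covariates(covariates[screen_cols], keep = keep)
  prey_sp <- setdiff(names(histories), predator)
  if (is.null(prey_formula))
    prey_formula <- stats::reformulate(c(intersect(
      c("humans", "livestock", "dist_road", "dist_settlement", "canopy", "forest"),
      scr$retained), "competitors"))
  prey <- run_prey_stage(histories[prey_sp], covariates,
                         psi_formula = prey_formula, seed = seed, ...)
  if (is.null(tiger_psi_formula)) {
    fitted_sp <- names(prey$fits)
    pick <- intersect(c("blue_bull", "gaur", "wild_pig"), fitted_sp)
    if (length(pick) == 0) pick <- fitted_sp
    tiger_psi_formula <- stats::reformulate(c(
      intersect(c("forest", "humans", "livestock"), scr$retained),
      paste0("psi_", pick)))
  }
  tiger <- run_tiger_stage(histories[[predator]], covariates,
                           prey$psi_sites[, names(prey$fits), drop = FALSE],
                           psi_formula = tiger_psi_formula,
                           det_formula = tiger_det_formula,
                           seed = seed + 1000, ...)
  table2 <- summary(tiger)
  psi_sites <- predict(tiger, type = "psi")
  psi_sites <- cbind(site = covariates$site, psi_sites)
  grid <- idw(covariates[, c("x", "y")], psi_sites$mean, cell = cell,
              power = power)
  report <- list(seed = seed, predator = predator,
                 settings = tiger$settings,
                 screen_retained = scr$retained,
                 skipped_prey = prey$skipped,
                 converged = c(vapply(prey$fits, `[[`, logical(1), "converged"),
                               tiger = tiger$converged))
  structure(list(screen = scr, prey = prey, tiger = tiger,
                 table1 = prey$table1, table2 = table2,
                 significant = is_significant(table2),
                 psi_sites = psi_sites, grid = grid, report = report),
            class = "tiger_pipeline")
}

#' @export
print.tiger_pipeline <- function(x, ...) {
  cat("Two-stage space-use pipeline\n")
  cat("  screened covariates retained:",
      paste(x$screen$retained, collapse = ", "), "\n")
  cat("  prey fitted:", paste(names(x$prey$fits), collapse = ", "), "\n")
  if (length(x$prey$skipped))
    cat("  prey skipped (no detections):",
        paste(x$prey$skipped, collapse = ", "), "\n")
  cat(sprintf("  predator space use (mean of sites): %.3f; detection: %.3f\n",
              x$table2["psi", "mean"], x$table2["p", "mean"]))
  sig <- names(x$significant)[x$significant &
                                grepl("^psi_", names(x$significant))]
  sig <- setdiff(sig, "psi_(Intercept)")
  cat("  significant space-use covariates:",
      if (length(sig)) paste(sub("^psi_", "", sig), collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Write pipeline outputs to plain-text files
#'
#' Writes `table1.csv`, `table2.csv`, `psi_sites.csv`, `psi_grid.asc` and
#' `report.json` to a directory.
#'
#' @param x a `"tiger_pipeline"` result.
#' @param dir output directory (created if missing).
#' @return invisibly, `dir`.
#' @export
write_pipeline <- function(x, dir) {
  stopifnot(inherits(x, "tiger_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(x$table1))
    utils::write.csv(x$table1, file.path(dir, "table1.csv"), row.names = FALSE)
  utils::write.csv(cbind(parameter = rownames(x$table2),
                         as.data.frame(x$table2)),
                   file.path(dir, "table2.csv"), row.names = FALSE)
  utils::write.csv(x$psi_sites, file.path(dir, "psi_sites.csv"), row.names = FALSE)
  write_asc(x$grid, file.path(dir, "psi_grid.asc"))
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(x$report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
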