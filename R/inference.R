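#' Principal component analysis of climate variables
#'
#' Eigen-decomposition of the correlation matrix of the climate table, after
#' square-root transforming the named skewed variables (precipitation-type
#' variables, typically) and standardising everything to zero mean and unit
#' variance. Component signs are fixed so each component's largest-magnitude
#' loading is positive.
#'
#' @param climate data frame or matrix of climate variables, cells as rows
#'   (row names = cell ids).
#' @param sqrt_vars character vector of column names to square-root
#'   transform first.
#' @param n_components number of components to return scores for.
#' @return list of class `climate_pca`: `scores` (cells x n_components),
#'   `loadings`, `proportion` (variance share per retained component),
#'   `cumulative`, `sdev` (all components).
#' @export
climate_pca <- function(climate, sqrt_vars = character(), n_components = 4L) {
  X <- as.matrix(climate)
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  if (ncol(X) < n_components) stop("fewer variables than components")
  if (nrow(X) <= ncol(X)) stop("need more cells than climate variables")
  bad <- setdiff(sqrt_vars, colnames(X))
  if (length(bad)) stop("unknown sqrt_vars: ", paste(bad, collapse = ", "))
  for (v in sqrt_vars) {
    if (any(X[, v] < 0)) stop("sqrt transform of negative values in ", v)
    X[, v] <- sqrt(X[, v])
  }
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant climate variable(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  Z <- scale(X)
  ev <- eigen(stats::cor(X), symmetric = TRUE)
  load <- ev$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- Z %*% load
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_components)))
  dimnames(load) <- list(colnames(X), colnames(scores))
  prop <- ev$values / sum(ev$values)
  structure(list(scores = scores, loadings = load,
                 proportion = prop[seq_len(n_components)],
                 cumulative = cumsum(prop)[seq_len(n_components)],
                 sdev = sqrt(pmax(ev$values, 0))),
            class = "climate_pca")
}

#' @export
print.climate_pca <- function(x, ...) {
  cat("climate PCA:", ncol(x$scores), "components,",
      sprintf("%.1f%%", 100 * x$cumulative[length(x$cumulative)]),
      "of variance\n")
  invisible(x)
}

new_design <- function(X, cells) {
  X <- as.matrix(X)
  rownames(X) <- cells
  structure(list(x = X, cells = cells), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design matrix:", nrow(x$x), "cells x", ncol(x$x), "predictors (",
      paste(utils::head(colnames(x$x), 6L), collapse = ", "),
      if (ncol(x$x) > 6L) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Environment design matrix
#'
#' Predictors of the environment-only model: the first four climate
#' principal components with quadratic terms, mean elevation with a
#' quadratic term, elevation range, and log-transformed landmass area —
#' 12 columns (the intercept is added at fit time).
#'
#' @param env data frame with row names = cell ids and columns
#'   `elevation`, `elevation_range`, `area` (positive).
#' @param climate_scores matrix of PC scores (cells x >= 4) with matching
#'   row names, e.g. from [climate_pca()].
#' @return a `design_matrix`.
#' @export
build_env_design <- function(env, climate_scores) {
  cells <- rownames(env)
  if (is.null(cells)) stop("env needs cell row names")
  sc <- as.matrix(climate_scores)
  if (!identical(rownames(sc), cells)) {
    if (is.null(rownames(sc)) || !setequal(rownames(sc), cells)) {
      stop("climate scores do not align with env cells")
    }
    sc <- sc[cells, , drop = FALSE]
  }
  if (ncol(sc) < 4L) stop("need at least four climate components")
  need <- c("elevation", "elevation_range", "area")
  miss <- setdiff(need, colnames(env))
  if (length(miss)) stop("env lacks columns: ", paste(miss, collapse = ", "))
  if (any(env$area <= 0)) stop("landmass area must be positive")
  pc <- sc[, 1:4, drop = FALSE]
  X <- cbind(pc, pc^2,
             elev = env$elevation, elev2 = env$elevation^2,
             elev_range = env$elevation_range, log_area = log(env$area))
  colnames(X) <- c(paste0("PC", 1:4), paste0("PC", 1:4, "_sq"),
                   "elev", "elev_sq", "elev_range", "log_area")
  new_design(X, cells)
}

#' Biogeographic-isolation design matrix (second-order trend surface)
#'
#' Treats the NMDS embedding of phylogenetic turnover as a coordinate
#' surface: all axes, their squares, and all pairwise products. With the
#' default three axes this is 9 columns; other k generalises with a warning.
#'
#' @param ord an `nmds_fit` (or a coordinate matrix with cell row names).
#' @return a `design_matrix`.
#' @export
build_isolation_design <- function(ord) {
  pts <- if (inherits(ord, "nmds_fit")) ord$points else as.matrix(ord)
  if (is.null(rownames(pts))) stop("coordinates need cell row names")
  k <- ncol(pts)
  if (k != 3L) {
    warning("k = ", k, " axes: building the generalised second-order surface")
  }
  nm <- paste0("ax", seq_len(k))
  X <- pts
  colnames(X) <- nm
  X <- cbind(X, X^2)
  colnames(X)[(k + 1):(2 * k)] <- paste0(nm, "_sq")
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        X <- cbind(X, pts[, i] * pts[, j])
        colnames(X)[ncol(X)] <- paste0(nm[i], "_", nm[j])
      }
    }
  }
  new_design(X, rownames(pts))
}

#' Discrete-realm design matrix
#'
#' Dummy coding of realm labels (alphabetically first level as reference);
#' the categorical counterpart the continuous isolation surface is compared
#' against.
#'
#' @param realms named character vector or factor, names = cell ids.
#' @return a `design_matrix` with `r - 1` columns for `r` realms.
#' @export
build_realm_design <- function(realms) {
  if (is.null(names(realms))) stop("realm labels need cell names")
  f <- factor(as.character(realms), levels = sort(unique(as.character(realms))))
  if (nlevels(f) < 2L) stop("need at least two realms")
  X <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
  colnames(X) <- paste0("realm_", levels(f)[-1L])
  new_design(X, names(realms))
}

#' Ordinary least squares fit with adjusted R-squared
#'
#' Fits `y ~ 1 + X` by QR least squares and records the quantities the
#' variance partition needs. Rank deficiency is an error that names the
#' aliased columns rather than silently dropping them.
#'
#' @param design a `design_matrix` (or plain matrix with cell row names).
#' @param y named numeric response aligned with the design cells.
#' @return object of class `ols_fit`: `coefficients`, `fitted`, `residuals`,
#'   `r_squared`, `adj_r_squared`, `n`, `p`.
#' @export
ols_fit <- function(design, y) {
  X <- if (inherits(design, "design_matrix")) design$x else as.matrix(design)
  if (!is.null(names(y))) {
    if (!setequal(names(y), rownames(X))) stop("response cells do not match design")
    y <- y[rownames(X)]
  } else if (length(y) != nrow(X)) stop("response length does not match design")
  if (anyNA(y) || anyNA(X)) stop("missing values in response or design")
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) stop("need n > p + 1 observations")
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    aliased <- colnames(Xi)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(Xi))]]
    stop("rank-deficient design; collinear columns: ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  fitted <- drop(Xi %*% beta)
  resid <- y - fitted
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("constant response")
  r2 <- 1 - sum(resid^2) / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(coefficients = beta,
                 fitted = stats::setNames(fitted, rownames(X)),
                 residuals = stats::setNames(resid, rownames(X)),
                 r_squared = r2, adj_r_squared = adj, n = n, p = p),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, p = %d, R2 = %.4f, adj R2 = %.4f\n",
              x$n, x$p, x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients

#' @export
residuals.ols_fit <- function(object, ...) object$residuals

#' @export
fitted.ols_fit <- function(object, ...) object$fitted

#' Variance partition between environment and isolation
#'
#' Fits the environment-only, isolation-only and combined (global) models
#' and decomposes the global adjusted R-squared into the fraction explained
#' by isolation only (`unique_iso`), by environment only (`unique_env`) and
#' by both (`shared`). Fractions can be slightly negative — a known property
#' of adjusted-R-squared partitions — and are reported as-is.
#'
#' @param y named response vector.
#' @param x_env,x_iso `design_matrix` objects on the same cells.
#' @return object of class `variance_partition` with the three fractions,
#'   the three adjusted R-squared values, and the three `ols_fit`s.
#' @export
variance_partition <- function(y, x_env, x_iso) {
  cells <- x_env$cells
  if (!identical(cells, x_iso$cells)) {
    if (!setequal(cells, x_iso$cells)) stop("designs cover different cells")
    x_iso <- new_design(x_iso$x[cells, , drop = FALSE], cells)
  }
  fit_env <- ols_fit(x_env, y)
  fit_iso <- ols_fit(x_iso, y)
  # predictors shared verbatim between the two blocks (or otherwise aliased)
  # are dropped from the combined model instead of failing it: the global
  # adjusted R-squared is unchanged by removing exact redundancies
  Xb <- cbind(x_env$x, x_iso$x)
  qr_b <- qr(cbind(1, Xb))
  if (qr_b$rank < ncol(Xb) + 1L) {
    keep <- sort(qr_b$pivot[seq_len(qr_b$rank)])
    keep <- setdiff(keep, 1L) - 1L
    warning("dropping ", ncol(Xb) - length(keep),
            " aliased column(s) from the combined model")
    Xb <- Xb[, keep, drop = FALSE]
  }
  both <- new_design(Xb, cells)
  fit_global <- ols_fit(both, y)
  a_env <- fit_env$adj_r_squared
  a_iso <- fit_iso$adj_r_squared
  a_glob <- fit_global$adj_r_squared
  structure(list(adj_env = a_env, adj_iso = a_iso, adj_global = a_glob,
                 unique_iso = a_glob - a_env,
                 unique_env = a_glob - a_iso,
                 shared = a_env + a_iso - a_glob,
                 fit_env = fit_env, fit_iso = fit_iso,
                 fit_global = fit_global),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("variance partition (adjusted R2):\n")
  cat(sprintf("  environment only: %7.4f\n", x$unique_env))
  cat(sprintf("  isolation only:   %7.4f\n", x$unique_iso))
  cat(sprintf("  shared:           %7.4f\n", x$shared))
  cat(sprintf("  global:           %7.4f\n", x$adj_global))
  invisible(x)
}

#' Per-cell residual difference between nested models
#'
#' `|residual in the environment-only model| - |residual in the global
#' model|` for each cell. Positive values mark cells where adding the
#' isolation surface moved the fit closer to the observation.
#'
#' @param fit_env,fit_global `ols_fit` objects on the same cells and
#'   response.
#' @return named numeric vector of residual differences.
#' @export
residual_difference <- function(fit_env, fit_global) {
  ce <- names(fit_env$residuals); cg <- names(fit_global$residuals)
  if (!identical(ce, cg)) {
    if (!setequal(ce, cg)) stop("fits cover different cells")
    fit_global$residuals <- fit_global$residuals[ce]
  }
  abs(fit_env$residuals) - abs(fit_global$residuals)
}

#' Observed-versus-predicted summary for a cell subset
#'
#' Medians and ranges of model predictions and observations over a subset
#' of cells (a region of interest), and the percent shortfall of the
#' observed median relative to the predicted one:
#' `(median_pred - median_obs) / median_pred * 100`.
#'
#' @param fit an `ols_fit`.
#' @param y named observed response.
#' @param cells character vector of cell ids (non-empty).
#' @return list with `median_predicted`, `range_predicted`,
#'   `median_observed`, `range_observed`, `percent_difference`, `n`.
#' @export
prediction_summary <- function(fit, y, cells) {
  if (length(cells) == 0L) stop("empty cell subset")
  miss <- setdiff(cells, names(fit$fitted))
  if (length(miss)) stop("cells not in fit: ", paste(miss, collapse = ", "))
  pred <- fit$fitted[cells]
  obs <- y[cells]
  mp <- stats::median(pred); mo <- stats::median(obs)
  list(median_predicted = mp, range_predicted = range(pred),
       median_observed = mo, range_observed = range(obs),
       percent_difference = (mp - mo) / mp * 100, n = length(cells))
}

#' Adjusted-R-squared gain of adding a predictor block
#'
#' Screening helper: does adding `extra` columns to a base design raise the
#' adjusted R-squared by more than `threshold` (default 1 percentage point)?
#'
#' @param y named response.
#' @param base,extra `design_matrix` objects on the same cells.
#' @param threshold minimum gain to flag as worth keeping.
#' @return list with `adj_base`, `adj_full`, `gain`, `keep`.
#' @export
delta_r2_screen <- function(y, base, extra, threshold = 0.01) {
  full <- new_design(cbind(base$x, extra$x[base$cells, , drop = FALSE]),
                     base$cells)
  f0 <- ols_fit(base, y)
  f1 <- ols_fit(full, y)
  gain <- f1$adj_r_squared - f0$adj_r_squared
  list(adj_base = f0$adj_r_squared, adj_full = f1$adj_r_squared,
       gain = gain, keep = gain > threshold)
}
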