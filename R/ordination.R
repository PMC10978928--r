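#' Least-squares monotone (isotonic) regression with tie averaging
#'
#' Fits non-decreasing values to `distances` under the ordering given by
#' `dissimilarities`, the workhorse inside Kruskal's non-metric scaling.
#' Tied dissimilarities are handled by averaging: fitted values are constant
#' within a tie block, which makes the weighted pool-adjacent-violators fit
#' equivalent to an unweighted isotonic fit on block means expanded to block
#' sizes (that expansion is what [stats::isoreg()] receives).
#'
#' @param dissimilarities numeric vector defining the order constraint.
#' @param distances numeric vector of the same length to be fitted.
#' @return fitted values, non-decreasing in the dissimilarity order, aligned
#'   with the input order.
#' @export
monotone_regression <- function(dissimilarities, distances) {
  if (length(distances) == 0L) stop("empty input")
  if (length(dissimilarities) != length(distances)) stop("length mismatch")
  make_monotone_fitter(dissimilarities)(distances)
}

# Precomputes the dissimilarity order and tie blocks once, returning a fast
# per-configuration fitter (the order never changes inside an NMDS run).
make_monotone_fitter <- function(dissimilarities) {
  ord <- order(dissimilarities)
  blk <- cumsum(c(TRUE, diff(dissimilarities[ord]) > 0))
  nb <- tabulate(blk)
  n <- length(dissimilarities)
  function(distances) {
    y <- distances[ord]
    bm <- rowsum(y, blk, reorder = FALSE) / nb
    fit <- stats::isoreg(bm[blk])$yf
    out <- numeric(n)
    out[ord] <- fit
    out
  }
}

config_distances <- function(coords) {
  as.vector(stats::dist(coords))
}

#' Kruskal stress-1 of a configuration against a dissimilarity matrix
#'
#' `sqrt( sum (d - dhat)^2 / sum d^2 )` over unordered pairs, where `d` are
#' configuration distances and `dhat` their monotone-regression fit on the
#' dissimilarity order. Invariant to rotation, reflection, translation and
#' uniform scaling of the configuration.
#'
#' @param coords numeric matrix of coordinates, rows in the order of `d`'s
#'   items.
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @return stress value in \[0, 1\].
#' @export
stress1 <- function(coords, d) {
  diss <- as.vector(stats::as.dist(d))
  dd <- config_distances(coords)
  if (length(dd) != length(diss)) stop("coords do not match d")
  if (all(dd == 0)) stop("all configuration distances are zero")
  dhat <- monotone_regression(diss, dd)
  sqrt(sum((dd - dhat)^2) / sum(dd^2))
}

# One Guttman (majorisation) update of the configuration toward dhat.
guttman_update <- function(X, dhat_mat) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  ratio <- matrix(0, n, n)
  nz <- D > 0
  ratio[nz] <- dhat_mat[nz] / D[nz]
  B <- -ratio
  diag(B) <- rowSums(ratio)
  (B %*% X) / n
}

nmds_single_start <- function(fit_mono, diss_mat_idx, X, max_iter, tol) {
  n <- nrow(X)
  trace <- numeric(0)
  dd <- config_distances(X)
  dhat <- fit_mono(dd)
  stress <- sqrt(sum((dd - dhat)^2) / sum(dd^2))
  trace <- stress
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dhat_mat <- matrix(0, n, n)
    dhat_mat[diss_mat_idx] <- dhat
    dhat_mat <- dhat_mat + t(dhat_mat)
    target <- guttman_update(X, dhat_mat)
    # backtracking step toward the Guttman target guarantees a
    # non-increasing stress trace even when the normaliser shifts
    alpha <- 1
    repeat {
      X_new <- X + alpha * (target - X)
      dd_new <- config_distances(X_new)
      if (!all(dd_new == 0)) {
        dhat_new <- fit_mono(dd_new)
        stress_new <- sqrt(sum((dd_new - dhat_new)^2) / sum(dd_new^2))
        if (stress_new <= stress + 1e-15) break
      }
      alpha <- alpha / 2
      if (alpha < 1e-8) { X_new <- X; dd_new <- dd
        dhat_new <- dhat; stress_new <- stress; break }
    }
    delta <- stress - stress_new
    X <- X_new; dd <- dd_new; dhat <- dhat_new; stress <- stress_new
    trace <- c(trace, stress)
    if (delta >= 0 && delta < tol) { converged <- TRUE; break }
  }
  list(coords = X, stress = stress, trace = trace, converged = converged)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a dissimilarity matrix in `k` dimensions by iterative stress
#' minimisation: monotone regression of configuration distances on the
#' dissimilarity order alternated with Guttman majorisation steps (with
#' backtracking, so the recorded stress trace never increases). The first
#' start is the classical metric-scaling configuration; the remaining
#' `n_starts - 1` are seeded random configurations. The best solution is
#' centred and rotated to principal axes, with each axis's sign fixed so its
#' largest-magnitude score is positive, making axis labels deterministic.
#'
#' @param d a `dist` or symmetric dissimilarity matrix.
#' @param k number of axes (default 3).
#' @param n_starts number of starting configurations (>= 1).
#' @param max_iter maximum iterations per start.
#' @param tol convergence tolerance on the stress decrease.
#' @param seed integer seed for the random starts.
#' @return an object of class `nmds_fit`: `points` (n x k), `stress`,
#'   `traces` (per-start stress sequences), `best_start`, `converged`,
#'   `k`, `seed`, `items`.
#' @export
nmds <- function(d, k = 3L, n_starts = 20L, max_iter = 500L,
                 tol = 1e-7, seed = 1L) {
  Dm <- as.matrix(stats::as.dist(d))
  n <- nrow(Dm)
  if (n < k + 1L) stop("need more items than axes")
  if (n_starts < 1L) stop("n_starts must be >= 1")
  items <- rownames(Dm)
  if (is.null(items)) items <- as.character(seq_len(n))
  diss_vec <- as.vector(stats::as.dist(Dm))
  idx <- which(lower.tri(Dm))

  starts <- vector("list", n_starts)
  cmd <- suppressWarnings(stats::cmdscale(Dm, k = k))
  if (ncol(cmd) < k) {
    cmd <- cbind(cmd, matrix(stats::rnorm(n * (k - ncol(cmd)), sd = 1e-4), n))
  }
  starts[[1L]] <- cmd
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  span <- max(diss_vec)
  if (n_starts > 1L) {
    for (s in seq(2L, n_starts)) {
      starts[[s]] <- matrix(stats::runif(n * k, -span, span), n, k)
    }
  }

  fit_mono <- make_monotone_fitter(diss_vec)
  runs <- lapply(starts, function(X0) {
    nmds_single_start(fit_mono, idx, X0, max_iter, tol)
  })
  best <- which.min(vapply(runs, `[[`, numeric(1L), "stress"))
  fit <- runs[[best]]

  X <- scale(fit$coords, center = TRUE, scale = FALSE)
  sv <- svd(X)
  X <- sv$u %*% diag(sv$d, k)
  for (j in seq_len(k)) {
    i <- which.max(abs(X[, j]))
    if (X[i, j] < 0) X[, j] <- -X[, j]
  }
  dimnames(X) <- list(items, paste0("NMDS", seq_len(k)))
  structure(list(points = X, stress = fit$stress,
                 traces = lapply(runs, `[[`, "trace"),
                 best_start = best,
                 converged = fit$converged, k = k, seed = seed,
                 items = items,
                 n_starts = n_starts),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS: %d items, k = %d, stress-1 = %.4f (best of %d starts%s)\n",
              length(x$items), x$k, x$stress, x$n_starts,
              if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' @export
plot.nmds_fit <- function(x, axes = c(1L, 2L), col = 1, ...) {
  graphics::plot(x$points[, axes[1L]], x$points[, axes[2L]],
                 xlab = colnames(x$points)[axes[1L]],
                 ylab = colnames(x$points)[axes[2L]], col = col, ...)
  invisible(x)
}
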