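#' Run the biogeographic-isolation analysis end to end
#'
#' Chains the full analysis: phylogenetic beta diversity turnover over all
#' cell pairs, NMDS embedding (k axes) of the turnover matrix, construction
#' of the environment design (climate PCA + elevation terms + log area) and
#' the isolation design (second-order trend surface on the NMDS axes, or
#' realm dummies in realm mode), then for each response variable an OLS fit
#' of the environment-only, isolation-only and combined models, the adjusted
#' R-squared variance partition, the per-cell residual-difference map, and
#' observed-versus-predicted summaries for any named cell subsets.
#'
#' @param tree a `phylo` covering the occurrence species.
#' @param occurrence cell-by-species 0/1 matrix.
#' @param env data frame with row names = cell ids, columns `elevation`,
#'   `elevation_range`, `area` and the climate variables.
#' @param climate_cols names of the climate columns in `env`.
#' @param sqrt_cols climate columns to square-root transform (skewed,
#'   precipitation-like ones).
#' @param traits optional [trait_table()] enabling the functional responses.
#' @param realms optional named cell-to-realm labels (required in realm
#'   mode; also used to define the default prediction subsets).
#' @param responses subset of `"richness"`, `"pd"`, `"fric"`,
#'   `"func_turnover"`.
#' @param m functional-space axes (used when functional responses are on).
#' @param k NMDS axes.
#' @param n_starts,max_iter NMDS settings.
#' @param realm_mode replace the continuous isolation surface by realm
#'   dummy variables.
#' @param subsets named list of cell-id vectors for prediction summaries;
#'   defaults to one subset per realm when `realms` is given.
#' @param seed integer seed (NMDS starts).
#' @param out_dir optional directory; when set, all intermediates are
#'   written there (CSV/JSON/newick).
#' @param verbose print stage progress.
#' @return an object of class `pipeline_report`.
#' @export
run_pipeline <- function(tree, occurrence, env, climate_cols,
                         sqrt_cols = character(), traits = NULL,
                         realms = NULL,
                         responses = c("richness", "pd", "fric",
                                       "func_turnover"),
                         m = 4L, k = 3L, n_starts = 4L, max_iter = 300L,
                         realm_mode = FALSE, subsets = NULL, seed = 1L,
                         out_dir = NULL, verbose = FALSE) {
  responses <- match.arg(responses, several.ok = TRUE)
  occurrence <- as_occurrence(occurrence)
  log <- list()
  t_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log[[length(log) + 1L]] <<- list(
      stage = name, seconds = as.numeric(Sys.time() - t0, units = "secs"))
    if (verbose) message(sprintf("[%s] %.1fs", name,
                                 log[[length(log)]]$seconds))
    out
  }

  pb <- stage("phylobeta", phylobeta_matrix(tree, occurrence,
                                            drop_empty = TRUE))
  occurrence <- occurrence[pb$cells, , drop = FALSE]
  env <- env[pb$cells, , drop = FALSE]
  if (anyNA(env)) stop("environment table has missing values")

  ord <- stage("nmds", nmds(pb$sim, k = k, n_starts = n_starts,
                            max_iter = max_iter, seed = seed))
  pca <- stage("climate_pca",
               climate_pca(env[, climate_cols, drop = FALSE],
                           sqrt_vars = sqrt_cols))
  x_env <- stage("env_design", build_env_design(env, pca$scores))
  iso_note <- NULL
  if (realm_mode) {
    if (is.null(realms)) stop("realm_mode needs realm labels")
    x_iso <- stage("realm_design",
                   build_realm_design(realms[pb$cells]))
    iso_note <- "isolation design replaced by discrete realm dummies"
  } else {
    x_iso <- stage("isolation_design", build_isolation_design(ord))
  }

  space <- NULL
  if (any(c("fric", "func_turnover") %in% responses)) {
    if (is.null(traits)) stop("functional responses need a trait table")
    space <- stage("functional_space",
                   build_functional_space(traits, m = m))
  }
  resp <- list()
  if ("richness" %in% responses) {
    resp$richness <- stats::setNames(rowSums(occurrence), pb$cells)
  }
  if ("pd" %in% responses) resp$pd <- pb$pd
  if ("fric" %in% responses) {
    resp$fric <- stage("fric", {
      v <- vapply(pb$cells, function(cl) {
        as.numeric(functional_richness(
          space, colnames(occurrence)[occurrence[cl, ] == 1L]))
      }, numeric(1L))
      stats::setNames(v, pb$cells)
    })
  }
  if ("func_turnover" %in% responses) {
    resp$func_turnover <- stage("func_turnover",
                                mean_functional_turnover(occurrence, space))
  }

  if (is.null(subsets) && !is.null(realms)) {
    rl <- realms[pb$cells]
    subsets <- split(names(rl), as.character(rl))
  }

  results <- list()
  for (nm in names(resp)) {
    y <- resp[[nm]]
    keep <- names(y)[!is.na(y)]
    n_dropped <- length(y) - length(keep)
    xe <- new_design(x_env$x[keep, , drop = FALSE], keep)
    xi <- new_design(x_iso$x[keep, , drop = FALSE], keep)
    vp <- stage(paste0("partition_", nm),
                variance_partition(y[keep], xe, xi))
    rd <- residual_difference(vp$fit_env, vp$fit_global)
    ps <- NULL
    if (!is.null(subsets)) {
      ps <- lapply(subsets, function(cl) {
        cl <- intersect(cl, keep)
        if (length(cl) == 0L) return(NULL)
        prediction_summary(vp$fit_env, y[keep], cl)
      })
    }
    results[[nm]] <- list(partition = vp, residual_difference = rd,
                          prediction = ps, n_cells = length(keep),
                          n_dropped = n_dropped)
  }

  report <- structure(
    list(results = results, nmds = ord, climate_pca = pca,
         phylobeta = pb, space = space,
         responses = names(resp), realm_mode = realm_mode,
         iso_note = iso_note, seed = seed, k = k,
         n_cells = length(pb$cells), dropped_cells = pb$dropped,
         log = log,
         total_seconds = as.numeric(Sys.time() - t_all, units = "secs")),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report: %d cells, k = %d, stress = %.3f%s\n",
              x$n_cells, x$k, x$nmds$stress,
              if (x$realm_mode) " [realm mode]" else ""))
  for (nm in x$responses) {
    vp <- x$results[[nm]]$partition
    cat(sprintf(paste0("  %-14s adjR2 global %.3f | iso-only %+.3f",
                       " env-only %+.3f shared %+.3f\n"),
                nm, vp$adj_global, vp$unique_iso, vp$unique_env, vp$shared))
  }
  invisible(x)
}

# Strip run-dependent timing so that reports are comparable across reruns.
report_fingerprint <- function(report) {
  r <- unclass(report)
  r$log <- NULL
  r$total_seconds <- NULL
  r$results <- lapply(r$results, function(res) {
    res$partition$fit_env <- res$partition$fit_env[
      c("coefficients", "r_squared", "adj_r_squared")]
    res
  })
  r
}

#' Write a pipeline report and its intermediates to disk
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_distance_csv(report$phylobeta$sim, file.path(dir, "pbsim.csv"))
  write_coordinates_csv(report$nmds, file.path(dir, "nmds_coords.csv"))
  summ <- list(seed = report$seed, k = report$k,
               stress = report$nmds$stress,
               n_cells = report$n_cells,
               realm_mode = report$realm_mode,
               iso_note = report$iso_note,
               climate_cumulative_variance =
                 report$climate_pca$cumulative,
               responses = lapply(report$results, function(res) {
                 vp <- res$partition
                 list(adj_env = vp$adj_env, adj_iso = vp$adj_iso,
                      adj_global = vp$adj_global,
                      unique_iso = vp$unique_iso,
                      unique_env = vp$unique_env, shared = vp$shared,
                      n_cells = res$n_cells, n_dropped = res$n_dropped)
               }),
               log = report$log)
  jsonlite::write_json(summ, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(report$results)) {
    rd <- report$results[[nm]]$residual_difference
    utils::write.csv(data.frame(cell = names(rd), residual_difference = rd),
                     file.path(dir, paste0("residual_difference_", nm,
                                           ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' The bundled demonstration world
#'
#' A small synthetic world (6 x 6 grid, 36 cells, three realms with the
#' third thinned to half its environmental expectation) used by examples
#' and fast end-to-end checks.
#'
#' @param seed master seed.
#' @param isolation_factor rho for the isolated realm.
#' @return a `synthetic_world`.
#' @export
demo_world <- function(seed = 101L, isolation_factor = 0.5) {
  build_world(world_config(
    n_rows = 6L, n_cols = 6L, realm_spans = c(2L, 2L, 2L),
    species_per_realm = 30L, mixing = 0.15,
    isolation_factor = isolation_factor, seed = seed))
}
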