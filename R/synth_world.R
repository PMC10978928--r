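# Synthetic-world generator: a grid of cells with an environmental gradient,
# realm-structured species pools evolving on a simulated phylogeny, and two
# independently tunable kinds of biogeographic isolation — clade endemism
# (via the mixing fraction) and richness thinning (via the isolation factor
# rho) — so pipeline inferences can be validated against known ground truth.

#' Configuration of a synthetic world
#'
#' Defaults define the package's standard validation world: a 12 x 18 grid
#' (216 cells) split column-wise into three realms (8/8/2 columns), 320
#' species per realm, a latitudinal environment with six climate variables
#' derived from two latent gradients, range-map-like niche-thresholded
#' occupancy, and an optional richness-thinning factor `isolation_factor`
#' (rho) applied to every species in the designated isolated realm (the
#' small third realm by default).
#'
#' @param n_rows,n_cols grid dimensions.
#' @param realm_spans columns per realm (must sum to `n_cols`).
#' @param species_per_realm species contributed by each realm.
#' @param mixing fraction in \[0, 1\] of the total pool drawn from a
#'   cosmopolitan (range-unrestricted) clade instead of realm endemics.
#' @param birth,death rates of the birth-death tree simulation per clade.
#' @param trait_rate Brownian variance per unit branch length.
#' @param cat_rate transition rate of the categorical trait's Markov chain.
#' @param niche_breadth Gaussian niche standard deviation on the unit
#'   latitude scale.
#' @param occupancy_max occupancy probability at the niche optimum.
#' @param isolation_factor rho in (0, 1]: occupancy multiplier in the
#'   isolated realm (1 = no effect).
#' @param isolated_realm index of the realm receiving the thinning.
#' @param env_noise standard deviation of cell-level climate noise.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a list of class `world_config`.
#' @export
world_config <- function(n_rows = 12L, n_cols = 18L,
                         realm_spans = c(8L, 8L, 2L),
                         species_per_realm = 320L,
                         mixing = 0.1,
                         birth = 1, death = 0,
                         trait_rate = 1, cat_rate = 2,
                         niche_breadth = 0.25,
                         occupancy_max = 0.85,
                         isolation_factor = 1,
                         isolated_realm = length(realm_spans),
                         env_noise = 0.05,
                         seed = 1L) {
  if (sum(realm_spans) != n_cols) stop("realm_spans must partition the columns")
  if (mixing < 0 || mixing > 1) stop("mixing must be in [0, 1]")
  if (isolation_factor <= 0 || isolation_factor > 1) {
    stop("isolation_factor must be in (0, 1]")
  }
  if (birth < 0 || death < 0 || trait_rate < 0 || cat_rate < 0) {
    stop("rates must be >= 0")
  }
  if (isolated_realm < 1L || isolated_realm > length(realm_spans)) {
    stop("isolated_realm out of range")
  }
  structure(as.list(environment()), class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat(sprintf(paste0("world config: %dx%d grid, %d realms, %d species/realm,",
                     " mixing %.2f, rho %.2f (realm %d), seed %d\n"),
              x$n_rows, x$n_cols, length(x$realm_spans),
              x$species_per_realm, x$mixing, x$isolation_factor,
              x$isolated_realm, x$seed))
  invisible(x)
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 13L + stage
}

# Species accounting: how many endemics per realm and how many cosmopolitans.
species_plan <- function(config) {
  total <- length(config$realm_spans) * config$species_per_realm
  n_cosmo <- round(config$mixing * total)
  n_realms <- length(config$realm_spans)
  endemics <- rep((total - n_cosmo) %/% n_realms, n_realms)
  left <- (total - n_cosmo) %% n_realms
  if (left > 0) endemics[seq_len(left)] <- endemics[seq_len(left)] + 1L
  list(endemics = endemics, n_cosmo = n_cosmo, total = total)
}

clade_newick <- function(n, label_prefix, birth, death, height, stem,
                         retries = 10L) {
  labels <- sprintf("%s_%03d", label_prefix, seq_len(n))
  if (n == 1L) return(sprintf("%s:%g", labels, height + stem))
  tr <- NULL
  for (i in seq_len(retries)) {
    tr <- tryCatch(ape::rphylo(n, birth, death, fossils = FALSE),
                   error = function(e) NULL)
    if (!is.null(tr)) break
  }
  if (is.null(tr)) stop("tree simulation failed after ", retries, " retries")
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * height / depth
  tr$tip.label <- labels
  txt <- ape::write.tree(tr)
  sub(";$", sprintf(":%g", stem), txt)
}

#' Simulate a realm-structured ultrametric phylogeny
#'
#' One birth-death clade per realm (its endemics) plus one cosmopolitan
#' clade sized by the mixing fraction, grafted onto a common root: each
#' clade is rescaled to height 0.7 and attached by a stem of 0.3, giving an
#' ultrametric tree of depth 1. Tips are tagged with their realm of origin
#' (`"shared"` for the cosmopolitan clade).
#'
#' @param config a [world_config()].
#' @return list with `tree` (a `phylo`) and `realm_of` (named character
#'   vector tagging every tip).
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "world_config"))
  plan <- species_plan(config)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(stage_seed(config$seed, 1L))
  parts <- character()
  tags <- character()
  for (k in seq_along(plan$endemics)) {
    if (plan$endemics[k] == 0L) next
    pref <- sprintf("R%d", k)
    parts <- c(parts, clade_newick(plan$endemics[k], pref,
                                   config$birth, config$death, 0.7, 0.3))
    tags <- c(tags, stats::setNames(
      rep(sprintf("realm%d", k), plan$endemics[k]),
      sprintf("%s_%03d", pref, seq_len(plan$endemics[k]))))
  }
  if (plan$n_cosmo > 0L) {
    parts <- c(parts, clade_newick(plan$n_cosmo, "SH",
                                   config$birth, config$death, 0.7, 0.3))
    tags <- c(tags, stats::setNames(rep("shared", plan$n_cosmo),
                                    sprintf("SH_%03d",
                                            seq_len(plan$n_cosmo))))
  }
  txt <- if (length(parts) == 1L) {
    # single clade: drop the stem, scale to depth 1
    tr <- ape::read.tree(text = paste0(
      "(", parts, ");"))
    tr <- ape::read.tree(text = ape::write.tree(tr))
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    ape::write.tree(tr)
  } else {
    paste0("(", paste(parts, collapse = ","), ");")
  }
  tree <- read_newick(txt)
  list(tree = tree, realm_of = tags[tree$tip.label])
}

#' Evolve a trait table on a simulated phylogeny
#'
#' Continuous body mass evolves by geometric Brownian motion (declared with
#' a log transform in the schema), a four-part diet percentage block is the
#' softmax of independent Brownian traits scaled to sum to 100, and a
#' three-state foraging stratum evolves by a symmetric continuous-time
#' Markov chain.
#'
#' @param tree a `phylo` object.
#' @param config a [world_config()].
#' @return a [trait_table()].
#' @export
evolve_traits <- function(tree, config) {
  stopifnot(inherits(config, "world_config"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(stage_seed(config$seed, 2L))
  n <- length(tree$tip.label)
  rate <- config$trait_rate
  if (rate > 0) {
    bm <- simulate_bm_traits(tree, 5L, rate = rate)
  } else {
    bm <- matrix(0, n, 5L, dimnames = list(tree$tip.label, NULL))
  }
  body_mass <- exp(3 + bm[, 1L])
  diet <- exp(bm[, 2:5])
  diet <- diet / rowSums(diet) * 100
  colnames(diet) <- paste0("diet_", c("invertebrates", "fruit", "seeds",
                                      "vertebrates"))
  states <- c("aerial", "arboreal", "ground")
  if (config$cat_rate > 0) {
    strat <- ape::rTraitDisc(tree, model = "ER", k = 3L,
                             rate = config$cat_rate, states = states)
  } else {
    strat <- factor(rep(states[1L], n), levels = states)
    names(strat) <- tree$tip.label
  }
  df <- data.frame(body_mass = body_mass, diet,
                   stratum = as.character(strat[tree$tip.label]),
                   row.names = tree$tip.label,
                   check.names = FALSE)
  types <- stats::setNames(c("continuous", rep("percentage", 4L),
                             "categorical"), names(df))
  trait_table(df, types, transforms = c(body_mass = "log"))
}

#' Generate a complete synthetic world
#'
#' Builds all pipeline inputs with known ground truth: the realm-structured
#' phylogeny, the trait table, a cell-by-species occurrence matrix from
#' Gaussian niche matching on the latitudinal gradient (masked by realm
#' endemism and thinned by rho in the isolated realm), the cell environment
#' table (six climate variables from two latent gradients, elevation,
#' elevation range, landmass area), and realm labels.
#'
#' @param config a [world_config()].
#' @param empty_cell_retries redraws allowed for a cell with no species.
#' @return a list of class `synthetic_world`: `tree`, `realm_of_species`,
#'   `traits`, `occurrence`, `env`, `realm_of_cell`, `truth`.
#' @export
build_world <- function(config = world_config(), empty_cell_retries = 20L) {
  stopifnot(inherits(config, "world_config"))
  sim <- simulate_tree(config)
  traits <- evolve_traits(sim$tree, config)
  species <- sim$tree$tip.label
  realm_of_species <- sim$realm_of

  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(stage_seed(config$seed, 3L))

  nr <- config$n_rows; nc <- config$n_cols
  cells <- sprintf("c%02d_%02d", rep(seq_len(nr), each = nc),
                   rep(seq_len(nc), nr))
  row_of <- rep(seq_len(nr), each = nc)
  col_of <- rep(seq_len(nc), nr)
  lat <- (row_of - 0.5) / nr
  realm_of_cell <- stats::setNames(
    sprintf("realm%d", rep(seq_along(config$realm_spans),
                           config$realm_spans))[col_of], cells)

  g1 <- lat                                   # thermal latitude gradient
  g2 <- sin(pi * lat)                         # humidity-like gradient
  ncell <- length(cells)
  noise <- function() stats::rnorm(ncell, 0, config$env_noise)
  clim <- cbind(
    temp1 = 30 - 25 * g1 + noise(),
    temp2 = 18 - 14 * g1 + 3 * g2 + noise(),
    temp3 = 10 * g1 * g1 + noise(),
    temp4 = 5 - 4 * g2 + noise(),
    precip1 = (1.2 * g2 + 0.2 + noise())^2 * 1000,
    precip2 = (0.8 * g2 + 0.5 * (1 - g1) + 0.2 + noise())^2 * 800)
  elevation <- 500 + stats::rnorm(ncell, 0, 150)
  elevation_range <- abs(stats::rnorm(ncell, 300, 100)) + 50
  area <- exp(stats::rnorm(ncell, log(1e5), 0.4))
  env <- data.frame(row = row_of, col = col_of, lat = lat, clim,
                    elevation = elevation,
                    elevation_range = elevation_range, area = area,
                    row.names = cells)

  optima <- stats::setNames(stats::runif(length(species)), species)
  # secondary, weakly selective niche axis on elevation: it varies the
  # composition from cell to cell (as topography does for real ranges)
  # while leaving richness totals mostly latitude-driven
  e01 <- (elevation - 200) / 600
  elev_opt <- stats::setNames(stats::runif(length(species)), species)
  sigma_e <- 0.5
  p_niche <- config$occupancy_max *
    exp(-outer(g1, optima, `-`)^2 / (2 * config$niche_breadth^2)) *
    exp(-outer(e01, elev_opt, `-`)^2 / (2 * sigma_e^2))
  mask <- outer(realm_of_cell, realm_of_species,
                function(rc, rs) rs == "shared" | rs == rc)
  iso_cells <- realm_of_cell == sprintf("realm%d", config$isolated_realm)
  p <- p_niche * mask
  dimnames(p) <- list(cells, species)
  p[iso_cells, ] <- p[iso_cells, ] * config$isolation_factor
  # range-map-like occupancy: one uniform draw per species thresholds its
  # niche curve, so each cell is occupied with exactly the probability p
  # but presences are spatially coherent (a contiguous latitudinal range),
  # as with real range maps, instead of independent cell-level coin flips
  u <- stats::runif(length(species))
  occ <- matrix(0L, nrow(p), ncol(p), dimnames = list(cells, species))
  occ[p >= rep(u, each = nrow(p))] <- 1L
  flagged <- character()
  for (cl in cells[rowSums(occ) == 0L]) {
    done <- FALSE
    for (r in seq_len(empty_cell_retries)) {
      draw <- stats::rbinom(ncol(occ), 1L, p[cl, ])
      if (sum(draw) > 0L) { occ[cl, ] <- draw; done <- TRUE; break }
    }
    if (!done) flagged <- c(flagged, cl)
  }
  truth <- list(config = unclass(config), optima = optima,
                elev_optima = elev_opt,
                isolated_cells = cells[iso_cells],
                stage_seeds = stats::setNames(
                  stage_seed(config$seed, 1:3),
                  c("tree", "traits", "occupancy")),
                empty_flagged = flagged)
  structure(list(tree = sim$tree, realm_of_species = realm_of_species,
                 traits = traits, occurrence = occ, env = env,
                 realm_of_cell = realm_of_cell, truth = truth),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("synthetic world: %d cells, %d species, ",
                     "richness median %g, rho %.2f\n"),
              nrow(x$occurrence), ncol(x$occurrence),
              stats::median(rowSums(x$occurrence)),
              x$truth$config$isolation_factor))
  invisible(x)
}

#' Write a synthetic world to disk in plain-text formats
#'
#' newick tree, occurrence/environment/realm CSVs, trait CSV with a JSON
#' schema sidecar, and a JSON truth record sufficient to regenerate the
#' world.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(world$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(world$occurrence, file.path(dir, "occurrence.csv"))
  utils::write.csv(world$env, file.path(dir, "environment.csv"))
  utils::write.csv(data.frame(cell = names(world$realm_of_cell),
                              realm = world$realm_of_cell),
                   file.path(dir, "realms.csv"), row.names = FALSE)
  utils::write.csv(world$traits$data, file.path(dir, "traits.csv"))
  jsonlite::write_json(
    list(types = as.list(world$traits$types),
         transforms = as.list(world$traits$transforms),
         weights = as.list(world$traits$weights)),
    file.path(dir, "traits_schema.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a world written by [write_world()]
#'
#' @param dir directory containing the world files.
#' @return a list with the same components as [build_world()] output
#'   (minus the realm tags of species, which live in the truth record).
#' @export
read_world <- function(dir) {
  tree <- read_newick(file = file.path(dir, "tree.nwk"))
  occ <- as.matrix(utils::read.csv(file.path(dir, "occurrence.csv"),
                                   row.names = 1L, check.names = FALSE))
  env <- utils::read.csv(file.path(dir, "environment.csv"), row.names = 1L)
  realms <- utils::read.csv(file.path(dir, "realms.csv"))
  schema <- jsonlite::read_json(file.path(dir, "traits_schema.json"),
                                simplifyVector = TRUE)
  tdf <- utils::read.csv(file.path(dir, "traits.csv"), row.names = 1L,
                         check.names = FALSE)
  tfm <- unlist(schema$transforms)
  tfm <- tfm[!is.na(tfm)]
  traits <- trait_table(tdf, types = unlist(schema$types),
                        transforms = if (length(tfm)) tfm else NULL,
                        weights = unlist(schema$weights))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(tree = tree, occurrence = as_occurrence(occ), env = env,
       realm_of_cell = stats::setNames(realms$realm, realms$cell),
       traits = traits, truth = truth)
}
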