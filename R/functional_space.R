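#' Construct a species-by-trait table with a typed schema
#'
#' Wraps a data frame of traits with the per-column metadata the Gower
#' dissimilarity needs: the declared type of each trait (`"continuous"`,
#' `"percentage"` on a 0-100 scale, or `"categorical"`), an optional variance
#' -stabilising transform for continuous traits (`"log"` or `"sqrt"`, applied
#' before range scaling; body mass is the usual log case), and a non-negative
#' weight (default 1).
#'
#' @param data data frame, one row per species, with species ids as row names.
#' @param types named character vector declaring every column's type.
#' @param transforms optional named character vector (`"log"`/`"sqrt"`) for
#'   continuous columns.
#' @param weights optional named numeric vector of per-trait weights.
#' @return an object of class `trait_table`.
#' @export
trait_table <- function(data, types, transforms = NULL, weights = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data frame")
  if (is.null(rownames(data))) stop("species ids must be row names")
  if (!setequal(names(types), names(data))) {
    stop("`types` must name every trait column exactly once")
  }
  ok <- c("continuous", "percentage", "categorical")
  if (!all(types %in% ok)) {
    stop("trait types must be one of: ", paste(ok, collapse = ", "))
  }
  for (nm in names(data)) {
    if (types[[nm]] == "percentage") {
      v <- data[[nm]]
      if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 100)) {
        stop("percentage trait '", nm, "' must lie in [0, 100]")
      }
    }
    if (types[[nm]] == "continuous" && !is.numeric(data[[nm]])) {
      stop("continuous trait '", nm, "' must be numeric")
    }
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, ncol(data)),
                                                   names(data))
  if (any(weights < 0)) stop("trait weights must be >= 0")
  tr <- stats::setNames(rep(NA_character_, ncol(data)), names(data))
  if (!is.null(transforms)) {
    bad <- setdiff(names(transforms), names(data)[types == "continuous"])
    if (length(bad)) stop("transforms only apply to continuous traits: ",
                          paste(bad, collapse = ", "))
    tr[names(transforms)] <- transforms
  }
  structure(list(data = data, types = types[names(data)],
                 transforms = tr, weights = weights[names(data)],
                 species = rownames(data)),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait table:", nrow(x$data), "species x", ncol(x$data), "traits (",
      paste(sprintf("%s:%d", names(table(x$types)), table(x$types)),
            collapse = ", "), ")\n")
  invisible(x)
}

transform_continuous <- function(v, transform) {
  if (is.na(transform)) return(v)
  switch(transform,
         log = {
           if (any(v <= 0)) stop("log transform requires positive values")
           log(v)
         },
         sqrt = {
           if (any(v < 0)) stop("sqrt transform requires non-negative values")
           sqrt(v)
         },
         stop("unknown transform: ", transform))
}

#' Gower dissimilarity over a mixed trait table
#'
#' Per-trait dissimilarity is `|x_i - x_j| / range` for continuous traits
#' (after any declared transform) and for percentage traits (pre-scaled to
#' \[0, 1\]), and simple 0/1 mismatch for categorical traits; the pairwise
#' dissimilarity is the weighted mean over traits. Traits with zero range in
#' the pool carry no information and are dropped with a warning.
#'
#' @param traits a [trait_table()].
#' @return a `dist` of Gower dissimilarities in \[0, 1\].
#' @export
gower_matrix <- function(traits) {
  stopifnot(inherits(traits, "trait_table"))
  n <- nrow(traits$data)
  if (n < 2L) stop("need at least two species")
  acc <- matrix(0, n, n)
  wsum <- 0
  dropped <- character()
  for (nm in names(traits$data)) {
    w <- traits$weights[[nm]]
    if (w == 0) next
    v <- traits$data[[nm]]
    if (traits$types[[nm]] == "categorical") {
      d <- outer(as.character(v), as.character(v), `!=`) * 1
    } else {
      if (traits$types[[nm]] == "percentage") v <- v / 100
      else v <- transform_continuous(v, traits$transforms[[nm]])
      rg <- diff(range(v))
      if (rg <= 0) { dropped <- c(dropped, nm); next }
      d <- abs(outer(v, v, `-`)) / rg
    }
    if (all(d == 0)) { dropped <- c(dropped, nm); next }
    acc <- acc + w * d
    wsum <- wsum + w
  }
  if (length(dropped)) {
    warning("dropping invariant trait(s): ", paste(dropped, collapse = ", "))
  }
  if (wsum == 0) stop("no trait varies across species")
  g <- acc / wsum
  dimnames(g) <- list(traits$species, traits$species)
  stats::as.dist(g)
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical Gower PCoA: eigen-decomposition of the double-centred matrix
#' `-1/2 J D^2 J`, coordinates scaled by the square root of the eigenvalues.
#' Negative eigenvalues (non-Euclidean input) are truncated and reported;
#' `correction = "lingoes"` instead adds the smallest constant to all squared
#' off-diagonal dissimilarities that makes the matrix Euclidean.
#'
#' @param d a `dist` or symmetric matrix.
#' @param m number of axes to retain (>= 2).
#' @param correction `"none"` (truncate) or `"lingoes"`.
#' @return list with `coordinates` (n x m, row names = item ids),
#'   `eigenvalues` (all of them, descending), `m`, `negative` (count of
#'   negative eigenvalues) and `correction`.
#' @export
pcoa_axes <- function(d, m = 4L, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  D <- as.matrix(d)
  if (m < 2L) stop("m must be >= 2")
  n <- nrow(D)
  if (n <= m) stop("need more items than axes")
  D2 <- D^2
  if (correction == "lingoes") {
    ev0 <- eigen(double_center(D2), symmetric = TRUE, only.values = TRUE)
    cst <- -min(ev0$values)
    if (cst > 1e-12) D2 <- D2 + 2 * cst * (1 - diag(n))
  }
  B <- double_center(D2)
  ev <- eigen(B, symmetric = TRUE)
  vals <- ev$values
  tol_ev <- max(abs(vals)) * 1e-8
  # zero eigenvalues yield legitimate (zero-variance) axes; materially
  # negative ones cannot be embedded and bound the usable dimensionality
  usable <- sum(vals > -tol_ev)
  if (usable < m) {
    stop(sprintf("only %d non-negative eigenvalue(s); choose m <= %d",
                 sum(vals > tol_ev), usable))
  }
  coords <- ev$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(vals[seq_len(m)], 0)), m)
  # deterministic axis signs: largest-magnitude score positive
  for (j in seq_len(m)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(m))
  list(coordinates = coords, eigenvalues = vals, m = m,
       negative = sum(vals < -max(vals) * 1e-10), correction = correction)
}

double_center <- function(D2) {
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% D2 %*% J
}

#' Build a functional trait space
#'
#' Chains [gower_matrix()] and [pcoa_axes()] and caches the convex hull of
#' the whole species pool, whose volume is the denominator of functional
#' richness. The default of four axes suits rich assemblages; reduced pools
#' (e.g. a bat-only analysis) typically use three.
#'
#' @param traits a [trait_table()].
#' @param m number of ordination axes (default 4).
#' @param correction passed to [pcoa_axes()].
#' @return an object of class `functional_space` with `coordinates`,
#'   `eigenvalues`, `m`, `pool_hull`, `pool_volume`, `species`.
#' @export
build_functional_space <- function(traits, m = 4L,
                                   correction = c("none", "lingoes")) {
  g <- gower_matrix(traits)
  px <- pcoa_axes(g, m = m, correction = correction)
  functional_space(px$coordinates, eigenvalues = px$eigenvalues)
}

#' Assemble a functional space from ready-made coordinates
#'
#' @param coordinates n x m numeric matrix with species row names (m >= 2).
#' @param eigenvalues optional eigenvalue vector for the record.
#' @return an object of class `functional_space`.
#' @export
functional_space <- function(coordinates, eigenvalues = NULL) {
  coordinates <- as.matrix(coordinates)
  m <- ncol(coordinates)
  if (m < 2L) stop("functional space needs >= 2 axes")
  if (is.null(rownames(coordinates))) stop("coordinates need species names")
  hull <- convex_hull(coordinates)
  if (is.null(hull)) stop("species pool does not span the trait space")
  structure(list(coordinates = coordinates, eigenvalues = eigenvalues,
                 m = m, pool_hull = hull, pool_volume = hull$volume,
                 species = rownames(coordinates)),
            class = "functional_space")
}

#' @export
print.functional_space <- function(x, ...) {
  cat(sprintf("functional space: %d species on %d axes, pool volume %g\n",
              length(x$species), x$m, x$pool_volume))
  invisible(x)
}

space_subset <- function(space, species) {
  species <- unique(as.character(species))
  missing <- setdiff(species, space$species)
  if (length(missing)) {
    stop("species not in functional space: ", paste(missing, collapse = ", "))
  }
  space$coordinates[species, , drop = FALSE]
}

#' Functional richness of an assemblage
#'
#' Volume of the convex hull of the assemblage's species in trait space,
#' expressed as a proportion of the pool hull volume. Assemblages with fewer
#' than `m + 1` species, or whose points do not span an m-volume, cannot have
#' a hull volume; they return `NA` with a `reason` attribute (`"too_few"` or
#' `"degenerate"`) so downstream stages can exclude and report them.
#'
#' @param space a [functional_space()].
#' @param species character vector of species ids.
#' @return proportion in \[0, 1\], or `NA` with attribute `reason`.
#' @export
functional_richness <- function(space, species) {
  stopifnot(inherits(space, "functional_space"))
  pts <- space_subset(space, species)
  if (nrow(pts) < space$m + 1L) {
    return(structure(NA_real_, reason = "too_few"))
  }
  h <- convex_hull(pts)
  if (is.null(h)) return(structure(NA_real_, reason = "degenerate"))
  h$volume / space$pool_volume
}

func_beta_from_volumes <- function(va, vb, vshared) {
  vshared <- min(vshared, va, vb)   # guard numerical overshoot
  a <- vshared
  b <- max(va - vshared, 0)
  c_ <- max(vb - vshared, 0)
  sor <- if (2 * a + b + c_ > 0) (b + c_) / (2 * a + b + c_) else 0
  mn <- min(b, c_)
  turn <- if (a + mn > 0) mn / (a + mn) else 0
  list(sor = sor, turnover = turn, nestedness = sor - turn,
       v_a = va, v_b = vb, v_shared = vshared)
}

#' Functional beta diversity between two assemblages
#'
#' Convex-hull analogue of the Sorensen partition: with `a` the volume shared
#' by the two assemblage hulls and `b`, `c` the volumes unique to each,
#' `sor = (b+c)/(2a+b+c)` is total functional dissimilarity,
#' `turnover = min(b,c)/(a+min(b,c))` is the replacement of functional space
#' not attributable to richness differences (0 when one hull is nested in
#' the other), and `nestedness = sor - turnover`.
#'
#' @param space a [functional_space()].
#' @param set_a,set_b character vectors of species ids.
#' @return a list of class `func_beta_pair` with `sor`, `turnover`,
#'   `nestedness`, `v_a`, `v_b`, `v_shared`; or `NA` with a `reason`
#'   attribute when either hull is undefined.
#' @export
functional_beta_pair <- function(space, set_a, set_b) {
  stopifnot(inherits(space, "functional_space"))
  pa <- space_subset(space, set_a)
  pb <- space_subset(space, set_b)
  if (nrow(pa) < space$m + 1L || nrow(pb) < space$m + 1L) {
    return(structure(NA_real_, reason = "too_few"))
  }
  ha <- convex_hull(pa); hb <- convex_hull(pb)
  if (is.null(ha) || is.null(hb)) {
    return(structure(NA_real_, reason = "degenerate"))
  }
  vs <- hull_intersection_volume(ha, hb)
  structure(func_beta_from_volumes(ha$volume, hb$volume, vs),
            class = "func_beta_pair")
}

#' @export
print.func_beta_pair <- function(x, ...) {
  cat(sprintf("functional beta: sor %.4f  turnover %.4f  nestedness %.4f\n",
              x$sor, x$turnover, x$nestedness))
  invisible(x)
}

#' Mean functional turnover of each cell against all others
#'
#' For every valid cell (one whose species span a hull in trait space), the
#' arithmetic mean of pairwise functional turnover against every other valid
#' cell; a cell-level measure of functional distinctiveness. Invalid cells
#' are excluded from both focal and partner roles and reported.
#'
#' @param occ occurrence matrix (see [as_occurrence()]).
#' @param space a [functional_space()].
#' @return named numeric vector over all cells (`NA` for excluded ones),
#'   with attribute `excluded` naming them.
#' @export
mean_functional_turnover <- function(occ, space) {
  occ <- as_occurrence(occ)
  stopifnot(inherits(space, "functional_space"))
  cells <- rownames(occ)
  hulls <- vector("list", length(cells))
  names(hulls) <- cells
  for (cl in cells) {
    sp <- colnames(occ)[occ[cl, ] == 1L]
    if (length(sp) >= space$m + 1L) {
      pts <- space_subset(space, sp)
      hulls[[cl]] <- convex_hull(pts)
    }
  }
  valid <- cells[!vapply(hulls, is.null, logical(1L))]
  if (length(valid) < 2L) stop("fewer than two cells with a defined hull")
  k <- length(valid)
  turn <- matrix(0, k, k, dimnames = list(valid, valid))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      ha <- hulls[[valid[i]]]; hb <- hulls[[valid[j]]]
      fb <- func_beta_from_volumes(ha$volume, hb$volume,
                                   hull_intersection_volume(ha, hb))
      turn[i, j] <- turn[j, i] <- fb$turnover
    }
  }
  out <- stats::setNames(rep(NA_real_, length(cells)), cells)
  out[valid] <- rowSums(turn) / (k - 1L)
  structure(out, excluded = setdiff(cells, valid))
}
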