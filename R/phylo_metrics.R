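#' Read a phylogeny from a newick string or file
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' ape `phylo` object and is what every branch-length-based function in this
#' package consumes. Branch lengths are required on all non-root edges; a
#' missing root edge length is treated as 0 (the root stub never enters any
#' branch set). Ultrametricity is accepted but not required; use
#' [validate_phylogeny()] to check it explicitly.
#'
#' @param text a newick string, or `NULL` if `file` is given.
#' @param file path to a newick file.
#' @return an object of class `phylo`.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' sum(tr$edge.length)  # 6
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) stop("supply `text` or `file`")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf("malformed newick: %d '(' vs %d ')'", n_open, n_close))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error: unreadable tree")
  validate_phylogeny(tree, require_ultrametric = FALSE)
  tree
}

#' Validate a phylogeny for use as a branch-length substrate
#'
#' Checks the invariants the metric functions rely on: unique tip labels,
#' branch lengths present and non-negative, a single root. Ultrametricity is
#' only checked when `require_ultrametric = TRUE`.
#'
#' @param tree a `phylo` object.
#' @param require_ultrametric check root-to-tip depths are equal.
#' @return `tree`, invisibly; errors describe the violated invariant.
#' @export
validate_phylogeny <- function(tree, require_ultrametric = FALSE) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a `phylo` object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (length(tree$tip.label) > 1 &&
      length(tree$edge.length) < nrow(tree$edge)) {
    stop("branch lengths missing on some edges")
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0")
  }
  if (require_ultrametric && length(tree$tip.label) > 1 &&
      !ape::is.ultrametric(tree, option = 2)) {
    stop("tree is not ultrametric")
  }
  invisible(tree)
}

#' Coerce and validate a cell-by-species occurrence matrix
#'
#' @param x a matrix or data frame of 0/1 presences with cell identifiers as
#'   row names and species identifiers as column names.
#' @return an integer matrix with entries in \{0, 1\}.
#' @export
as_occurrence <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("occurrence input must be a matrix or data frame")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("occurrence matrix needs cell row names and species column names")
  }
  storage.mode(x) <- "integer"
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    stop("occurrence entries must be 0 or 1")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate cell identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate species identifiers")
  x
}

# Edge-by-tip incidence: entry (e, t) is TRUE when edge e lies on the path
# from tip t to the root. Rows follow tree$edge order.
edge_tip_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  inc_node <- matrix(FALSE, n_node, n_tip)
  inc_node[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  # postorder guarantees children are filled before their parent edge is read
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(ord))) {
    inc_node[ord[i, 1L], ] <- inc_node[ord[i, 1L], ] | inc_node[ord[i, 2L], ]
  }
  inc <- inc_node[tree$edge[, 2L], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  inc
}

check_species <- function(tree, species) {
  species <- unique(as.character(species))
  if (length(species) == 0L) stop("assemblage is empty")
  missing <- setdiff(species, tree$tip.label)
  if (length(missing)) {
    stop("species not in tree: ", paste(missing, collapse = ", "))
  }
  species
}

#' Branch set spanned by an assemblage
#'
#' Returns the edges on the union of root-to-tip paths for the given species,
#' under the rooted convention: paths run all the way to the tree root, not to
#' the most recent common ancestor of the subset, so the phylogenetic
#' diversity of the full species pool equals the total tree length. The
#' root's stub edge (ape's `root.edge`), when present, is never included.
#'
#' @param tree a `phylo` object.
#' @param species character vector of tip labels (non-empty, all in `tree`).
#' @return a list of class `branch_set` with `edges` (indices into
#'   `tree$edge`), `lengths`, and `total` (their sum).
#' @export
assemblage_branch_set <- function(tree, species) {
  validate_phylogeny(tree)
  species <- check_species(tree, species)
  inc <- edge_tip_incidence(tree)
  edges <- which(rowSums(inc[, species, drop = FALSE]) > 0)
  structure(list(edges = edges,
                 lengths = tree$edge.length[edges],
                 total = sum(tree$edge.length[edges])),
            class = "branch_set")
}

#' @export
print.branch_set <- function(x, ...) {
  cat("branch set:", length(x$edges), "edges, total length",
      format(x$total), "\n")
  invisible(x)
}

#' Faith's phylogenetic diversity
#'
#' Cumulative branch length connecting an assemblage's species on the
#' phylogeny (rooted convention; see [assemblage_branch_set()]).
#'
#' @inheritParams assemblage_branch_set
#' @return a single non-negative number.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' faith_pd(tr, c("A", "B"))  # 3
faith_pd <- function(tree, species) {
  assemblage_branch_set(tree, species)$total
}

# Vectorised Sorensen/Simpson/nestedness partition on branch lengths.
# Degenerate pairs (both branch sets of zero total length) yield 0 + warning.
phylobeta_from_abc <- function(a, b, c_) {
  m <- pmin(b, c_)
  denom_sor <- 2 * a + b + c_
  zero <- denom_sor <= 0
  if (any(zero)) {
    warning("pair(s) with zero total branch length; returning 0 for them")
  }
  sim <- ifelse(a + m > 0, m / (a + m), 0)
  sor <- ifelse(zero, 0, (b + c_) / denom_sor)
  list(sim = sim, sor = sor, nes = sor - sim)
}

#' Pairwise phylogenetic beta diversity between two assemblages
#'
#' Branch-length analogue of the Sorensen dissimilarity and its partition
#' into turnover and nestedness. With `a` the shared branch length and
#' `b`, `c` the branch lengths unique to each assemblage:
#' \deqn{sim = min(b,c) / (a + min(b,c)),\quad sor = (b+c)/(2a+b+c),\quad
#'   nes = sor - sim.}
#' `sim` is the turnover component (the branch-length extension of Simpson's
#' index), insensitive to differences in phylogenetic alpha diversity; `nes`
#' captures dissimilarity due to one branch set nesting inside the other.
#'
#' @param tree a `phylo` object.
#' @param set_a,set_b character vectors of tip labels (non-empty).
#' @return a list of class `phylobeta_pair` with elements `sim`, `sor`,
#'   `nes` and the branch-length components `a`, `b`, `c`.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' phylobeta_pair(tr, c("A", "B"), c("A", "C"))$sim  # 1/3
phylobeta_pair <- function(tree, set_a, set_b) {
  bs_a <- assemblage_branch_set(tree, set_a)
  bs_b <- assemblage_branch_set(tree, set_b)
  len <- tree$edge.length
  shared <- intersect(bs_a$edges, bs_b$edges)
  a <- sum(len[shared])
  b <- bs_a$total - a
  c_ <- bs_b$total - a
  out <- phylobeta_from_abc(a, b, c_)
  structure(c(out, list(a = a, b = b, c = c_)), class = "phylobeta_pair")
}

#' @export
print.phylobeta_pair <- function(x, ...) {
  cat(sprintf("phylobetadiversity: sim %.4f  sor %.4f  nes %.4f\n",
              x$sim, x$sor, x$nes))
  invisible(x)
}

#' Phylogenetic beta diversity matrices for all pairs of cells
#'
#' Computes, for every pair of cells in an occurrence matrix, the turnover
#' (`sim`), total (`sor`) and nestedness (`nes`) components of phylogenetic
#' beta diversity. Branch sets are materialised once per cell as a
#' cell-by-edge incidence, so the whole computation reduces to three matrix
#' products regardless of the number of pairs.
#'
#' @param tree a `phylo` object whose tips cover the occurrence columns.
#' @param occ occurrence matrix (see [as_occurrence()]).
#' @param drop_empty drop cells with no species (with a warning) instead of
#'   erroring.
#' @return a list of class `phylobeta` with `sim`, `sor`, `nes` as `dist`
#'   objects, the retained `cells`, and any `dropped` cell ids.
#' @export
phylobeta_matrix <- function(tree, occ, drop_empty = FALSE) {
  validate_phylogeny(tree)
  occ <- as_occurrence(occ)
  missing <- setdiff(colnames(occ), tree$tip.label)
  if (length(missing)) {
    stop("species not in tree: ", paste(missing, collapse = ", "))
  }
  empty <- rownames(occ)[rowSums(occ) == 0]
  if (length(empty)) {
    if (!drop_empty) {
      stop("cells without species: ", paste(empty, collapse = ", "),
           " (set drop_empty = TRUE to drop them)")
    }
    warning("dropping ", length(empty), " empty cell(s): ",
            paste(empty, collapse = ", "))
    occ <- occ[!(rownames(occ) %in% empty), , drop = FALSE]
  }
  if (nrow(occ) < 2L) stop("need at least two non-empty cells")

  inc <- edge_tip_incidence(tree)                     # edges x tips
  cell_edges <- (occ %*% t(inc[, colnames(occ), drop = FALSE])) > 0
  storage.mode(cell_edges) <- "double"
  len <- tree$edge.length
  shared <- cell_edges %*% (len * t(cell_edges))      # a_ij
  tot <- diag(shared)                                 # per-cell PD
  b <- matrix(tot, nrow(occ), nrow(occ)) - shared     # b_ij (rows unique)
  c_ <- t(b)
  comp <- phylobeta_from_abc(shared, b, c_)
  as_d <- function(m) {
    dimnames(m) <- list(rownames(occ), rownames(occ))
    diag(m) <- 0
    stats::as.dist(m)
  }
  structure(list(sim = as_d(comp$sim), sor = as_d(comp$sor),
                 nes = as_d(comp$nes), cells = rownames(occ),
                 pd = stats::setNames(tot, rownames(occ)),
                 dropped = empty),
            class = "phylobeta")
}

#' @export
print.phylobeta <- function(x, ...) {
  cat("phylobetadiversity over", length(x$cells), "cells\n")
  cat(sprintf("  sim: mean %.3f  range [%.3f, %.3f]\n",
              mean(x$sim), min(x$sim), max(x$sim)))
  if (length(x$dropped)) cat("  dropped empty cells:",
                             length(x$dropped), "\n")
  invisible(x)
}
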