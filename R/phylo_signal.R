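# Phylogenetic signal statistics. Both statistics work from the tip
# variance-covariance matrix C implied by shared branch lengths (C[i, j] =
# depth of the most recent common ancestor of tips i and j).

tip_vcv <- function(tree) {
  validate_phylogeny(tree)
  ape::vcv(tree)
}

#' Simulate Brownian-motion tip values on a tree
#'
#' Draws `n_sims` independent trait vectors from the multivariate normal
#' with covariance `rate * C`, `C` the tree's tip variance-covariance
#' matrix; the calibration standard for both signal statistics (Blomberg's K
#' is centred on 1, Fritz-Purvis D on 0, for such traits).
#'
#' @param tree a `phylo` object.
#' @param n_sims number of replicate traits.
#' @param rate Brownian variance per unit branch length.
#' @param root root state added to every tip.
#' @return tips x `n_sims` matrix with tip labels as row names.
#' @export
simulate_bm_traits <- function(tree, n_sims = 1L, rate = 1, root = 0) {
  C <- tip_vcv(tree)
  n <- nrow(C)
  L <- t(chol(C * rate + diag(1e-12, n)))
  X <- L %*% matrix(stats::rnorm(n * n_sims), n, n_sims) + root
  rownames(X) <- rownames(C)
  X
}

#' Blomberg's K for a continuous trait
#'
#' Ratio of the observed mean-squared-error ratio (trait variance among tips
#' over the phylogenetically corrected variance) to its Brownian-motion
#' expectation. K near 1 indicates as much signal as Brownian evolution on
#' the tree; K near 0, none. With `C` the tip variance-covariance matrix and
#' `a` the GLS root estimate `(1'C^-1 x)/(1'C^-1 1)`:
#' `K = [MSE0/MSE] / [(tr C - n / 1'C^-1 1) / (n - 1)]`,
#' `MSE0 = sum (x - a)^2 / (n - 1)`, `MSE = (x - a)' C^-1 (x - a) / (n - 1)`.
#'
#' @param tree a `phylo` object.
#' @param trait named numeric vector covering all tips.
#' @return object of class `phylo_signal` with `statistic`, `name = "K"`,
#'   `n`.
#' @export
blomberg_k <- function(tree, trait) {
  C <- tip_vcv(tree)
  trait <- align_trait(trait, rownames(C))
  if (stats::var(trait) == 0) stop("constant trait")
  n <- length(trait)
  Ci_x <- tryCatch(solve(C, cbind(trait, 1)),
                   error = function(e) stop("singular covariance matrix"))
  one_Ci_one <- sum(Ci_x[, 2L])
  a_hat <- sum(Ci_x[, 1L]) / one_Ci_one
  dev <- trait - a_hat
  mse0 <- sum(dev^2) / (n - 1)
  mse <- drop(crossprod(dev, solve(C, dev))) / (n - 1)
  expected <- (sum(diag(C)) - n / one_Ci_one) / (n - 1)
  structure(list(statistic = (mse0 / mse) / expected, name = "K", n = n),
            class = "phylo_signal")
}

align_trait <- function(trait, tips) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tips)) stop("trait length != tip count")
    names(trait) <- tips
  }
  miss <- setdiff(tips, names(trait))
  if (length(miss)) stop("trait missing for tips: ",
                         paste(miss, collapse = ", "))
  trait[tips]
}

# Sister-difference operator: row per internal node, so that
# colSums(abs(S %*% X)) gives the D numerator for each trait column of X.
# Nodal values are means of child values, accumulated tips-to-root.
sister_diff_operator <- function(tree) {
  n_tip <- length(tree$tip.label)
  if (!ape::is.binary(tree)) {
    stop("Fritz-Purvis D requires a binary tree; see ape::multi2di()")
  }
  n_node <- max(tree$edge)
  W <- matrix(0, n_node, n_tip)
  W[cbind(seq_len(n_tip), seq_len(n_tip))] <- 1
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  kids <- split(ord[, 2L], ord[, 1L])
  # order parents by the position of their last child edge: by then every
  # descendant's nodal value is already filled in
  last_pos <- tapply(seq_len(nrow(ord)), ord[, 1L], max)
  parents <- as.integer(names(sort(last_pos)))
  for (parent in parents) {
    ch <- kids[[as.character(parent)]]
    W[parent, ] <- colMeans(W[ch, , drop = FALSE])
  }
  S <- matrix(0, length(parents), n_tip)
  for (i in seq_along(parents)) {
    ch <- kids[[as.character(parents[i])]]
    S[i, ] <- W[ch[1L], ] - W[ch[2L], ]
  }
  colnames(S) <- tree$tip.label
  S
}

#' Fritz-Purvis D for a binary trait
#'
#' Phylogenetic signal for presence/absence traits. The observed sum of
#' sister-clade differences (`d_obs`, from nodal values obtained by averaging
#' tip states down the tree) is placed between two simulated expectations:
#' random tip shuffles (no signal; D = 1) and Brownian-motion simulations
#' thresholded to the observed prevalence (Brownian clumping; D = 0):
#' `D = (d_obs - mean d_BM) / (mean d_random - mean d_BM)`.
#' The rescaled value `1 - D` orients the statistic like Blomberg's K
#' (larger = more signal).
#'
#' @param tree a binary `phylo` object.
#' @param trait named 0/1 vector covering all tips, both states present.
#' @param n_sims size of each null ensemble (>= 100).
#' @param seed integer seed for both ensembles.
#' @return object of class `phylo_signal` with `statistic`, `name = "D"`,
#'   `rescaled` (= 1 - D), `d_obs`, `n_sims`, `seed`, `n`.
#' @export
fritz_purvis_d <- function(tree, trait, n_sims = 1000L, seed = 1L) {
  trait <- align_trait(trait, tree$tip.label)
  if (!all(trait %in% c(0, 1))) stop("trait must be 0/1")
  n1 <- sum(trait == 1)
  n <- length(trait)
  if (n1 == 0L || n1 == n) stop("trait is monomorphic")
  if (n_sims < 100L) stop("n_sims must be >= 100")
  S <- sister_diff_operator(tree)
  d_obs <- sum(abs(S %*% trait))

  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  perm <- replicate(n_sims, sample(trait))
  d_rand <- colSums(abs(S %*% perm))
  Z <- simulate_bm_traits(tree, n_sims)
  # threshold each simulation at the observed prevalence
  B <- apply(Z, 2L, function(z) as.numeric(rank(-z, ties.method = "first")
                                           <= n1))
  d_bm <- colSums(abs(S %*% B))
  D <- (d_obs - mean(d_bm)) / (mean(d_rand) - mean(d_bm))
  structure(list(statistic = D, name = "D", rescaled = 1 - D,
                 d_obs = d_obs, n_sims = n_sims, seed = seed, n = n),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("phylogenetic signal %s = %.4f (n = %d tips%s)\n",
              x$name, x$statistic, x$n,
              if (!is.null(x$rescaled))
                sprintf("; rescaled 1 - D = %.4f", x$rescaled) else ""))
  invisible(x)
}

#' Phylogenetic signal across a trait table
#'
#' Applies Blomberg's K to continuous and percentage traits and Fritz-Purvis
#' D to categorical ones; multi-state categorical traits are decomposed into
#' one-versus-rest binary traits, each scored separately.
#'
#' @param tree a `phylo` object.
#' @param traits a [trait_table()].
#' @param n_sims,seed passed to [fritz_purvis_d()].
#' @return data frame with one row per (trait, level) and columns `trait`,
#'   `level`, `statistic`, `value`, `rescaled`.
#' @export
signal_table <- function(tree, traits, n_sims = 1000L, seed = 1L) {
  stopifnot(inherits(traits, "trait_table"))
  rows <- list()
  for (nm in names(traits$data)) {
    v <- stats::setNames(traits$data[[nm]], traits$species)
    if (traits$types[[nm]] %in% c("continuous", "percentage")) {
      val <- if (stats::var(v) > 0) blomberg_k(tree, v)$statistic else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        trait = nm, level = NA_character_, statistic = "K",
        value = val, rescaled = val)
    } else {
      for (lv in sort(unique(as.character(v)))) {
        b <- stats::setNames(as.numeric(v == lv), names(v))
        if (sum(b) %in% c(0L, length(b))) next
        d <- fritz_purvis_d(tree, b, n_sims = n_sims, seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          trait = nm, level = lv, statistic = "D",
          value = d$statistic, rescaled = d$rescaled)
      }
    }
  }
  do.call(rbind, rows)
}
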