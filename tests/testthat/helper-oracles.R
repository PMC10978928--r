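# Independent oracles used across the suite. These deliberately avoid the
# package's internal machinery: branch sets are enumerated tip by tip from
# the raw edge table, and intersection volumes are estimated by rejection
# sampling.

# Brute-force branch set: climb parent pointers from each tip to the root,
# collecting edge row indices of tree$edge.
oracle_branch_set <- function(tree, species) {
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  edges <- integer(0)
  for (sp in species) {
    node <- match(sp, tree$tip.label)
    while (node != root) {
      e <- parent_edge[node]
      edges <- union(edges, e)
      node <- tree$edge[e, 1L]
    }
  }
  edges
}

oracle_phylobeta <- function(tree, set_a, set_b) {
  ea <- oracle_branch_set(tree, set_a)
  eb <- oracle_branch_set(tree, set_b)
  len <- tree$edge.length
  a <- sum(len[intersect(ea, eb)])
  b <- sum(len[setdiff(ea, eb)])
  c_ <- sum(len[setdiff(eb, ea)])
  sor <- (b + c_) / (2 * a + b + c_)
  sim <- min(b, c_) / (a + min(b, c_))
  list(sim = sim, sor = sor, nes = sor - sim, a = a, b = b, c = c_)
}

# Monte-Carlo intersection volume: uniform rejection sampling over the
# intersection of the two bounding boxes, chunked to bound memory.
oracle_mc_intersection <- function(pa, pb, n_points = 1e6, chunk = 2e5) {
  ha <- convex_hull(pa); hb <- convex_hull(pb)
  lo <- pmax(apply(pa, 2L, min), apply(pb, 2L, min))
  hi <- pmin(apply(pa, 2L, max), apply(pb, 2L, max))
  if (any(hi <= lo)) return(0)
  box <- prod(hi - lo)
  m <- length(lo)
  inside <- function(h, X) {
    rowSums(sweep(X %*% t(h$normals), 2L, h$offsets) > 1e-12) == 0
  }
  hits <- 0
  done <- 0
  while (done < n_points) {
    n <- min(chunk, n_points - done)
    X <- matrix(stats::runif(n * m, rep(lo, each = n), rep(hi, each = n)),
                n, m)
    hits <- hits + sum(inside(ha, X) & inside(hb, X))
    done <- done + n
  }
  hits / n_points * box
}

# Naive O(n^2) pool-adjacent-violators on block means, independent of
# stats::isoreg: repeatedly merge adjacent violating blocks.
oracle_isotonic <- function(diss, dist) {
  ord <- order(diss)
  x <- diss[ord]; y <- dist[ord]
  blocks <- lapply(seq_along(y), function(i) list(ids = i, val = y[i]))
  # first merge tie blocks in the dissimilarity
  i <- 1L
  while (i < length(blocks)) {
    if (x[blocks[[i + 1L]]$ids[1L]] == x[blocks[[i]]$ids[1L]]) {
      ids <- c(blocks[[i]]$ids, blocks[[i + 1L]]$ids)
      blocks[[i]] <- list(ids = ids, val = mean(y[ids]))
      blocks[[i + 1L]] <- NULL
    } else i <- i + 1L
  }
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(blocks)) {
      if (blocks[[i]]$val > blocks[[i + 1L]]$val + 1e-15) {
        ids <- c(blocks[[i]]$ids, blocks[[i + 1L]]$ids)
        blocks[[i]] <- list(ids = ids, val = mean(y[ids]))
        blocks[[i + 1L]] <- NULL
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  fit_sorted <- numeric(length(y))
  for (b in blocks) fit_sorted[b$ids] <- b$val
  out <- numeric(length(y))
  out[ord] <- fit_sorted
  out
}

oracle_stress1 <- function(coords, d) {
  diss <- as.vector(stats::as.dist(d))
  dd <- as.vector(stats::dist(coords))
  dhat <- oracle_isotonic(diss, dd)
  sqrt(sum((dd - dhat)^2) / sum(dd^2))
}

# The standard fixture tree used throughout: ((A:1,B:1):1,(C:1,D:1):1);
fixture_tree4 <- function() read_newick("((A:1,B:1):1,(C:1,D:1):1);")

# Standard climate column sets of synthetic worlds.
world_climate_cols <- c("temp1", "temp2", "temp3", "temp4",
                        "precip1", "precip2")
world_sqrt_cols <- c("precip1", "precip2")

random_assemblage <- function(tips, min_size = 1L) {
  n <- sample(seq(min_size, length(tips)), 1L)
  sample(tips, n)
}
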