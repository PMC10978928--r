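# Convex-hull geometry in m dimensions (m >= 2), used for functional
# richness and functional beta diversity. The hull is built by the
# incremental (beneath-beyond) algorithm, which yields a triangulated
# boundary: every facet is an (m-1)-simplex with an outward unit normal.
# That representation gives the volume (fan of simplices from an interior
# point) and the half-space form a.x <= b needed for hull intersection.

# Hyperplane through the m rows of V (m x m), oriented away from `inside`.
# Returns list(normal, offset) with unit normal, or NULL when degenerate.
facet_plane <- function(V, inside, tol) {
  m <- ncol(V)
  A <- sweep(V[-1L, , drop = FALSE], 2L, V[1L, ])
  qr_a <- qr(t(A))
  if (qr_a$rank < m - 1L) return(NULL)
  ns <- qr.Q(qr_a, complete = TRUE)[, m]
  b <- sum(ns * V[1L, ])
  side <- sum(ns * inside) - b
  if (abs(side) <= tol) return(NULL)   # interior point on facet plane
  if (side > 0) { ns <- -ns; b <- -b }
  list(normal = ns, offset = b)
}

# Pick m+1 affinely independent rows of P, greedily maximising spread.
initial_simplex <- function(P, tol) {
  n <- nrow(P); m <- ncol(P)
  i0 <- which.max(P[, 1L])
  j0 <- which.min(P[, 1L])
  if (i0 == j0) {
    d0 <- rowSums(sweep(P, 2L, P[i0, ])^2)
    j0 <- which.max(d0)
    if (max(d0) <= tol^2) return(NULL)
  }
  chosen <- c(i0, j0)
  for (step in seq_len(m - 1L)) {
    B <- t(sweep(P[chosen[-1L], , drop = FALSE], 2L, P[chosen[1L], ]))
    qr_b <- qr(B)
    resid <- sweep(P, 2L, P[chosen[1L], ]) -
      t(qr.fitted(qr_b, t(sweep(P, 2L, P[chosen[1L], ]))))
    rn <- sqrt(rowSums(resid^2))
    rn[chosen] <- 0
    k <- which.max(rn)
    if (rn[k] <= tol) return(NULL)
    chosen <- c(chosen, k)
  }
  chosen
}

#' Convex hull of a point set
#'
#' Builds the convex hull of `points` in full dimension, returning the
#' triangulated facets, their outward half-space form, the hull volume and
#' the hull vertices. Degenerate inputs (fewer than `m + 1` points, or points
#' that do not span an m-dimensional volume) return `NULL` — callers decide
#' whether that is an error or a missing value.
#'
#' @param points numeric matrix (rows = points, columns = dimensions, m >= 2).
#' @param tol degeneracy tolerance, scaled internally by the coordinate range.
#' @return `NULL` if degenerate, else a list of class `convex_hull` with
#'   `facets` (facet-by-m vertex-index matrix), `normals`, `offsets`
#'   (`normals %*% x <= offsets` describes the hull), `volume`, `vertices`
#'   (indices into `points`) and `interior` (a strictly interior point).
#' @export
convex_hull <- function(points, tol = 1e-9) {
  h <- convex_hull_once(points, tol)
  if (is.null(h) || hull_is_valid(h, points, tol)) return(h)
  # Highly degenerate inputs (many coplanar points, as arise for polytope
  # vertex sets) can leave the triangulated boundary non-manifold, which
  # corrupts the fan volume. A deterministic sub-tolerance joggle of the
  # coordinates restores general position at negligible volume error.
  P <- as.matrix(points)
  scale <- max(1, max(abs(P)))
  for (amp in scale * c(1e-8, 1e-7, 1e-6)) {
    PJ <- joggle(P, amp)
    h2 <- convex_hull_once(PJ, tol)
    if (!is.null(h2) && hull_is_valid(h2, PJ, tol)) {
      h2$joggled <- amp
      return(h2)
    }
  }
  warning("convex hull boundary is degenerate despite joggling; ",
          "volume may be inaccurate")
  h
}

# Combinatorial and geometric integrity of a triangulated hull boundary:
# every ridge shared by exactly 2 facets, the Euler characteristic of the
# boundary sphere, and no input point outside any facet. Degeneracy can
# otherwise leave a ridge-closed but self-overlapping triangulation whose
# facet fan miscounts the volume.
hull_is_valid <- function(h, points, tol) {
  m <- ncol(h$facets)
  nf <- nrow(h$facets)
  key_of <- function(rows) {
    vapply(rows, paste, character(1L), collapse = "_")
  }
  ridges <- character(nf * m)
  idx <- 0L
  for (f in seq_len(nf)) {
    v <- h$facets[f, ]
    for (d in seq_len(m)) {
      idx <- idx + 1L
      ridges[idx] <- paste(v[-d], collapse = "_")   # facet rows are sorted
    }
  }
  rtab <- table(ridges)
  if (any(rtab != 2L)) return(FALSE)
  n_v <- length(h$vertices)
  n_r <- length(rtab)
  euler_ok <- switch(as.character(m),
    "2" = n_v == nf,                         # polygon: V = E
    "3" = n_v - n_r + nf == 2L,              # sphere: V - E + F = 2
    {
      # m = 4: count distinct edges and triangles of the boundary complex
      edges <- unique(unlist(lapply(seq_len(nf), function(f) {
        v <- h$facets[f, ]
        key_of(utils::combn(v, 2L, simplify = FALSE))
      })))
      n_v - length(edges) + n_r - nf == 0L   # 3-sphere: V - E + F - C = 0
    })
  if (!isTRUE(euler_ok)) return(FALSE)
  P <- as.matrix(points)
  scale <- max(1, max(abs(P)))
  prot <- max(P %*% t(h$normals) - rep(h$offsets, each = nrow(P)))
  prot <= 20 * tol * scale
}

# Deterministic pseudo-random perturbation (independent of the RNG stream).
joggle <- function(P, amp) {
  n <- nrow(P); m <- ncol(P)
  i <- rep(seq_len(n), m)
  j <- rep(seq_len(m), each = n)
  x <- sin(i * 12.9898 + j * 78.233) * 43758.5453
  P + amp * matrix(x - floor(x) - 0.5, n, m)
}

convex_hull_once <- function(points, tol = 1e-9) {
  P <- as.matrix(points)
  storage.mode(P) <- "double"
  n <- nrow(P); m <- ncol(P)
  if (m < 2L) stop("need at least 2 dimensions")
  if (n < m + 1L) return(NULL)
  scale <- max(1, max(abs(P)))
  tol <- tol * scale

  sim <- initial_simplex(P, tol)
  if (is.null(sim)) return(NULL)
  inside <- colMeans(P[sim, , drop = FALSE])

  facets <- vector("list", 4L * m * (m + 1L))
  n_fac <- 0L
  add_facet <- function(idx) {
    pl <- facet_plane(P[idx, , drop = FALSE], inside, tol)
    if (is.null(pl)) return(invisible(NULL))
    n_fac <<- n_fac + 1L
    if (n_fac > length(facets)) length(facets) <<- 2L * n_fac
    facets[[n_fac]] <<- list(v = sort(idx), normal = pl$normal,
                             offset = pl$offset)
    invisible(NULL)
  }
  for (drop in seq_along(sim)) add_facet(sim[-drop])
  if (n_fac < m + 1L) return(NULL)

  rest <- setdiff(seq_len(n), sim)
  if (length(rest)) {
    ord <- rest[order(rowSums(sweep(P[rest, , drop = FALSE], 2L,
                                    inside)^2), decreasing = TRUE)]
    for (p_idx in ord) {
      p <- P[p_idx, ]
      vis <- logical(n_fac)
      for (f in seq_len(n_fac)) {
        vis[f] <- sum(facets[[f]]$normal * p) - facets[[f]]$offset > tol
      }
      if (!any(vis)) next
      # horizon ridges: ridges of visible facets not shared by two of them
      ridge_tab <- new.env(parent = emptyenv())
      for (f in which(vis)) {
        v <- facets[[f]]$v
        for (drop in seq_along(v)) {
          key <- paste(v[-drop], collapse = "_")
          cur <- ridge_tab[[key]]
          ridge_tab[[key]] <- if (is.null(cur)) v[-drop] else NA
        }
      }
      kept <- facets[seq_len(n_fac)][!vis]
      facets <- c(kept, vector("list", 4L * m))
      n_fac <- length(kept)
      for (key in ls(ridge_tab)) {
        ridge <- ridge_tab[[key]]
        if (length(ridge) == 1L && is.na(ridge[1L])) next
        add_facet(c(ridge, p_idx))
      }
    }
  }

  facets <- facets[seq_len(n_fac)]
  fac_mat <- do.call(rbind, lapply(facets, `[[`, "v"))
  normals <- do.call(rbind, lapply(facets, `[[`, "normal"))
  offsets <- vapply(facets, `[[`, numeric(1L), "offset")
  verts <- sort(unique(as.vector(fac_mat)))
  vol <- 0
  for (f in seq_len(n_fac)) {
    W <- sweep(P[fac_mat[f, ], , drop = FALSE], 2L, inside)
    vol <- vol + abs(det(W)) / factorial(m)
  }
  if (vol <= 0) return(NULL)
  structure(list(facets = fac_mat, normals = normals, offsets = offsets,
                 volume = vol, vertices = verts, interior = inside,
                 dim = m),
            class = "convex_hull")
}

#' @export
print.convex_hull <- function(x, ...) {
  cat(sprintf("convex hull: %dD, %d vertices, %d facets, volume %g\n",
              x$dim, length(x$vertices), nrow(x$facets), x$volume))
  invisible(x)
}

#' Volume of a convex hull of points
#'
#' @inheritParams convex_hull
#' @return the m-volume, or `NA_real_` when the points are degenerate.
#' @export
hull_volume <- function(points, tol = 1e-9) {
  h <- convex_hull(points, tol)
  if (is.null(h)) NA_real_ else h$volume
}

# Chebyshev centre of {x : A x <= b}: maximise r s.t. A x + r <= b
# (unit-normal rows). Returns the centre if the maximal r exceeds tol,
# else NULL. Free x is split into positive parts for boot::simplex.
chebyshev_center <- function(A, b, tol) {
  m <- ncol(A)
  A1 <- cbind(A, -A, 1)
  obj <- c(rep(0, 2L * m), 1)
  sol <- tryCatch(
    boot::simplex(a = obj, A1 = A1, b1 = b, maxi = TRUE),
    error = function(e) NULL)
  if (is.null(sol) || sol$solved != 1) return(NULL)
  r <- sol$value
  if (!is.finite(r) || r <= tol) return(NULL)
  x <- sol$soln[seq_len(m)] - sol$soln[m + seq_len(m)]
  list(center = x, radius = r)
}

#' Volume of the intersection of two convex hulls
#'
#' Exact intersection volume by the half-space method: the facet inequalities
#' of both hulls are pooled, a strictly interior point of the intersection is
#' located as the Chebyshev centre (linear programming), the vertices of the
#' intersection polytope are enumerated by point-hyperplane duality (the
#' convex hull of the dual points `a_i / (b_i - a_i . c)`), and the volume of
#' the vertex hull is returned. Returns 0 when the intersection has no
#' interior.
#'
#' @param points_a,points_b numeric matrices of points in the same dimension
#'   (2 to 4 are the intended range), each spanning full dimension.
#' @param tol geometric tolerance.
#' @return intersection volume (>= 0).
#' @export
#' @examples
#' sq <- function(x0) cbind(c(0, 0, 2, 2) + x0, c(0, 2, 0, 2) + x0)
#' hull_intersection_volume(sq(0), sq(1))  # 1
hull_intersection_volume <- function(points_a, points_b, tol = 1e-9) {
  ha <- if (inherits(points_a, "convex_hull")) points_a else
    convex_hull(points_a, tol)
  hb <- if (inherits(points_b, "convex_hull")) points_b else
    convex_hull(points_b, tol)
  if (is.null(ha) || is.null(hb)) {
    stop("degenerate input: points do not span the space")
  }
  if (ha$dim != hb$dim) stop("dimension mismatch")
  A <- rbind(ha$normals, hb$normals)
  b <- c(ha$offsets, hb$offsets)
  scale <- max(1, abs(b))
  cc <- chebyshev_center(A, b, tol * scale)
  if (is.null(cc)) return(0)
  c0 <- cc$center
  bshift <- b - drop(A %*% c0)          # all > 0 by construction
  dual <- A / bshift
  hd <- convex_hull(dual, tol)
  if (is.null(hd)) return(0)
  # each dual facet {y : g.y = h} maps to the primal vertex g/h + c0
  keep <- abs(hd$offsets) > tol
  V <- hd$normals[keep, , drop = FALSE] / hd$offsets[keep]
  V <- unique(round(sweep(V, 2L, c0, `+`), 10L))
  hv <- convex_hull(V, tol)
  if (is.null(hv)) 0 else hv$volume
}
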