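env_fixture <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(elevation = rnorm(n, 500, 100),
             elevation_range = runif(n, 50, 400),
             area = exp(rnorm(n, 11, 0.5)),
             row.names = sprintf("c%03d", seq_len(n)))
}

test_that("climate PCA handles correlation structure and signs", {
  set.seed(2)
  n <- 60
  base <- rnorm(n)
  clim <- cbind(v1 = base + rnorm(n, 0, 1e-8), v2 = 2 * base,
                v3 = rnorm(n), v4 = rnorm(n))
  rownames(clim) <- sprintf("c%03d", 1:n)
  p <- climate_pca(clim, n_components = 2L)
  expect_gt(p$proportion[1], 0.49)  # v1+v2 perfectly correlated pair
  expect_error(climate_pca(cbind(clim, v5 = 1), n_components = 2L),
               "constant")

  # scores equal the direct eigendecomposition oracle up to sign
  set.seed(3)
  clim2 <- matrix(rnorm(50 * 8), 50, 8,
                  dimnames = list(sprintf("c%02d", 1:50), paste0("v", 1:8)))
  p2 <- climate_pca(clim2, n_components = 4L)
  ev <- eigen(cor(clim2), symmetric = TRUE)
  ref <- scale(clim2) %*% ev$vectors[, 1:4]
  for (j in 1:4) {
    expect_equal(abs(p2$scores[, j]), abs(ref[, j]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_equal(sum(p2$sdev^2), 8, tolerance = 1e-9)
})

test_that("sqrt transform is applied to the flagged variables", {
  set.seed(4)
  n <- 40
  clim <- cbind(t1 = rnorm(n), t2 = rnorm(n), t3 = rnorm(n),
                pr = rexp(n)^2)
  rownames(clim) <- sprintf("c%03d", 1:n)
  p_raw <- climate_pca(clim, n_components = 4L)
  p_sqrt <- climate_pca(clim, sqrt_vars = "pr", n_components = 4L)
  clim_t <- clim; clim_t[, "pr"] <- sqrt(clim_t[, "pr"])
  p_ref <- climate_pca(clim_t, n_components = 4L)
  expect_equal(p_sqrt$scores, p_ref$scores)
  expect_false(isTRUE(all.equal(p_raw$scores, p_sqrt$scores)))
  expect_error(climate_pca(cbind(clim, neg = -abs(rnorm(n))),
                           sqrt_vars = "neg", n_components = 4L), "negative")
})

test_that("the environment design has the documented 12 columns", {
  env <- env_fixture(20)
  sc <- matrix(rnorm(80), 20, 4,
               dimnames = list(rownames(env), paste0("PC", 1:4)))
  X <- build_env_design(env, sc)
  expect_equal(ncol(X$x), 12L)
  # worked row: PC scores (1,0,0,0), elev 2, range 3, area e
  env1 <- data.frame(elevation = 2, elevation_range = 3, area = exp(1),
                     row.names = "c001")
  env1 <- rbind(env1, env1, env1)
  rownames(env1) <- paste0("c", 1:3)
  sc1 <- matrix(c(1, 0, 0, 0), 3, 4, byrow = TRUE,
                dimnames = list(rownames(env1), NULL))
  row <- build_env_design(env1, sc1)$x[1, ]
  expect_equal(unname(row), c(1, 0, 0, 0, 1, 0, 0, 0, 2, 4, 3, 1))

  env_bad <- env_fixture(20); env_bad$area[3] <- 0
  expect_error(build_env_design(env_bad, sc), "positive")
})

test_that("the isolation trend surface has 9 columns for k = 3", {
  pts <- matrix(c(1, 2, 3), 5, 3, byrow = TRUE,
                dimnames = list(paste0("c", 1:5), NULL))
  X <- build_isolation_design(pts)
  expect_equal(ncol(X$x), 9L)
  expect_equal(unname(X$x[1, ]), c(1, 2, 3, 1, 4, 9, 2, 3, 6))
  expect_equal(unname(build_isolation_design(
    matrix(0, 4, 3, dimnames = list(paste0("c", 1:4), NULL)))$x[1, ]),
    rep(0, 9))
  expect_warning(X2 <- build_isolation_design(
    matrix(rnorm(8), 4, 2, dimnames = list(paste0("c", 1:4), NULL))),
    "generalised")
  expect_equal(ncol(X2$x), 5L)  # 2 + 2 quadratics + 1 interaction
})

test_that("realm dummies use the alphabetical reference level", {
  realms <- setNames(c("Nea", "Aus", "Neo", "Aus", "Nea"),
                     paste0("c", 1:5))
  X <- build_realm_design(realms)
  expect_equal(ncol(X$x), 2L)
  expect_equal(colnames(X$x), c("realm_Nea", "realm_Neo"))
  expect_equal(unname(X$x[2, ]), c(0, 0))  # Aus = reference
  expect_equal(qr(X$x)$rank, 2L)
  expect_error(build_realm_design(setNames(rep("A", 4), paste0("c", 1:4))),
               "two realms")
})

test_that("OLS matches the normal-equations oracle", {
  set.seed(5)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("c%03d", 1:n), paste0("x", 1:4)))
  beta <- c(2, -1, 0.5, 0, 3)
  y <- setNames(drop(cbind(1, X) %*% beta) + rnorm(n, 0, 0.3),
                rownames(X))
  fit <- ols_fit(X, y)
  Xi <- cbind(1, X)
  ref <- drop(solve(t(Xi) %*% Xi, t(Xi) %*% y))
  expect_equal(unname(coef(fit)), unname(ref), tolerance = 1e-9)
  expect_equal(sum(residuals(fit)), 0, tolerance = 1e-8)
  expect_equal(fit$adj_r_squared,
               1 - (1 - fit$r_squared) * (n - 1) / (n - 4 - 1))

  # exact fit
  y2 <- setNames(drop(cbind(1, X) %*% beta), rownames(X))
  fit2 <- ols_fit(X, y2)
  expect_equal(fit2$r_squared, 1)
  expect_equal(unname(fitted(fit2)), unname(y2))

  # pure-noise response
  y3 <- setNames(rnorm(n), rownames(X))
  fit3 <- ols_fit(X, y3)
  expect_lt(fit3$r_squared, 0.25)
  expect_lt(fit3$adj_r_squared, fit3$r_squared)

  expect_error(ols_fit(cbind(X, dup = X[, 1]), y), "collinear")
})

test_that("variance partition identities hold exactly", {
  set.seed(6)
  n <- 80
  Xe <- matrix(rnorm(n * 3), n, 3,
               dimnames = list(sprintf("c%03d", 1:n), paste0("e", 1:3)))
  Xi <- matrix(rnorm(n * 2), n, 2,
               dimnames = list(rownames(Xe), paste0("i", 1:2)))
  de <- biogeodiv:::new_design(Xe, rownames(Xe))
  di <- biogeodiv:::new_design(Xi, rownames(Xe))
  y <- setNames(Xe[, 1] - 0.5 * Xi[, 2] + rnorm(n, 0, 0.5), rownames(Xe))
  vp <- variance_partition(y, de, di)
  expect_equal(vp$unique_env + vp$unique_iso + vp$shared, vp$adj_global,
               tolerance = 1e-12)
  expect_equal(vp$unique_iso, vp$adj_global - vp$adj_env, tolerance = 1e-12)

  # env-only signal with orthogonal iso block: unique_iso ~ 0
  y_env <- setNames(Xe[, 1] + rnorm(n, 0, 0.2), rownames(Xe))
  vp2 <- variance_partition(y_env, de, di)
  expect_lt(abs(vp2$unique_iso), 0.05)

  # identical blocks collapse to pure shared variance
  expect_warning(vp3 <- variance_partition(y, de, de), "aliased")
  expect_equal(vp3$shared, vp3$adj_global, tolerance = 1e-12)
  expect_equal(vp3$unique_env, 0, tolerance = 1e-12)
  expect_equal(vp3$unique_iso, 0, tolerance = 1e-12)
})

test_that("orthogonal noiseless signals split the variance cleanly", {
  n <- 64
  cells <- sprintf("c%03d", 1:n)
  e <- rep(c(-1, 1), each = n / 2)
  i <- rep(c(-1, 1), times = n / 2)
  de <- biogeodiv:::new_design(matrix(e, dimnames = list(cells, "e")), cells)
  di <- biogeodiv:::new_design(matrix(i, dimnames = list(cells, "i")), cells)
  y <- setNames(2 * e + i, cells)
  vp <- variance_partition(y, de, di)
  expect_equal(vp$adj_global, 1, tolerance = 1e-12)
  expect_lt(abs(vp$shared), 0.05)
  expect_equal(vp$unique_env, 4 / 5, tolerance = 0.05)
  expect_equal(vp$unique_iso, 1 / 5, tolerance = 0.05)
})

test_that("residual differences follow the per-cell definition", {
  set.seed(8)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(sprintf("c%03d", 1:n), c("a", "b")))
  y <- setNames(X[, 1] + rnorm(n), rownames(X))
  f1 <- ols_fit(X, y)
  expect_equal(unname(residual_difference(f1, f1)), rep(0, n))

  f_env <- list(residuals = c(c1 = -4, c2 = 1))
  f_glob <- list(residuals = c(c1 = 1, c2 = 1))
  expect_equal(unname(residual_difference(f_env, f_glob)), c(3, 0))
})

test_that("prediction summaries compute medians and percent difference", {
  fit <- list(fitted = c(a = 10, b = 20, c = 30))
  y <- c(a = 5, b = 10, c = 15)
  ps <- prediction_summary(fit, y, c("a", "b", "c"))
  expect_equal(ps$median_predicted, 20)
  expect_equal(ps$median_observed, 10)
  expect_equal(ps$percent_difference, 50)
  expect_error(prediction_summary(fit, y, character(0)), "empty")

  ps0 <- prediction_summary(list(fitted = y), y, names(y))
  expect_equal(ps0$percent_difference, 0)
})

test_that("the delta-R2 screen flags only useful predictor blocks", {
  set.seed(9)
  n <- 100
  cells <- sprintf("c%03d", 1:n)
  x1 <- rnorm(n); x2 <- rnorm(n); junk <- rnorm(n)
  y <- setNames(x1 + 0.8 * x2 + rnorm(n, 0, 0.5), cells)
  base <- biogeodiv:::new_design(matrix(x1, dimnames = list(cells, "x1")),
                                 cells)
  good <- biogeodiv:::new_design(matrix(x2, dimnames = list(cells, "x2")),
                                 cells)
  bad <- biogeodiv:::new_design(matrix(junk, dimnames = list(cells, "j")),
                                cells)
  expect_true(delta_r2_screen(y, base, good)$keep)
  expect_false(delta_r2_screen(y, base, bad)$keep)
})
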