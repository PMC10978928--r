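make_traits <- function(df, types, ...) trait_table(df, types, ...)

test_that("Gower dissimilarity matches hand-computed fixtures", {
  df <- data.frame(size = c(2, 7), guild = c("x", "x"),
                   row.names = c("s1", "s2"))
  # range scaling uses the pool range (2..7 here), so the continuous part is
  # |2-7|/5 = 1 — pin the fixture with an explicit third species instead
  df3 <- data.frame(size = c(0, 2, 7, 10), guild = c("x", "x", "x", "y"),
                    row.names = paste0("s", 1:4))
  g <- as.matrix(gower_matrix(make_traits(
    df3, c(size = "continuous", guild = "categorical"))))
  expect_equal(g["s2", "s3"], 0.25)  # (0.5 + 0)/2

  ident <- data.frame(a = c(1, 1), b = c("u", "u"),
                      row.names = c("s1", "s2"))
  expect_warning(
    expect_error(gower_matrix(make_traits(
      ident, c(a = "continuous", b = "categorical"))), "no trait varies"),
    "invariant")

  bin <- data.frame(b = c("u", "v"), row.names = c("s1", "s2"))
  expect_equal(as.vector(gower_matrix(make_traits(
    bin, c(b = "categorical")))), 1)
})

test_that("Gower entries are bounded, symmetric, zero-diagonal", {
  set.seed(17)
  df <- data.frame(mass = exp(rnorm(12, 2)),
                   diet = runif(12, 0, 100),
                   guild = sample(c("a", "b", "c"), 12, TRUE),
                   row.names = paste0("s", 1:12))
  g <- as.matrix(gower_matrix(make_traits(
    df, c(mass = "continuous", diet = "percentage", guild = "categorical"),
    transforms = c(mass = "log"))))
  expect_true(all(g >= 0 & g <= 1))
  expect_equal(g, t(g))
  expect_true(all(diag(g) == 0))
})

test_that("percentage traits outside [0,100] are rejected", {
  bad <- data.frame(p = c(-5, 50), row.names = c("s1", "s2"))
  expect_error(make_traits(bad, c(p = "percentage")), "\\[0, 100\\]")
})

test_that("PCoA of Euclidean distances recovers the configuration", {
  set.seed(19)
  P <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  px <- pcoa_axes(dist(P), m = 2)
  expect_equal(as.matrix(dist(px$coordinates)), as.matrix(dist(P)),
               tolerance = 1e-9)

  # 1-D arrangement: second eigenvalue vanishes
  line <- cbind(c(0, 1, 3, 7), 0)
  rownames(line) <- paste0("s", 1:4)
  px1 <- pcoa_axes(dist(line), m = 2)
  expect_lt(abs(px1$eigenvalues[2]), 1e-9)
})

test_that("PCoA agrees with the ape eigendecomposition oracle", {
  skip_if_not_installed("ape")
  set.seed(23)
  df <- data.frame(a = rnorm(8), b = runif(8, 0, 100),
                   c = sample(letters[1:3], 8, TRUE),
                   row.names = paste0("s", 1:8))
  g <- gower_matrix(make_traits(
    df, c(a = "continuous", b = "percentage", c = "categorical")))
  px <- pcoa_axes(g, m = 3)
  ref <- ape::pcoa(g)
  for (j in 1:3) {
    expect_equal(abs(px$coordinates[, j]), abs(ref$vectors[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("functional richness matches the triangle-in-square fixture", {
  sq <- cbind(c(0, 0, 2, 2), c(0, 2, 0, 2))
  pts <- rbind(sq, c(0, 1), c(1, 0))
  rownames(pts) <- paste0("s", 1:6)
  space <- functional_space(pts)
  expect_equal(space$pool_volume, 4)
  expect_equal(functional_richness(space, paste0("s", 1:6)), 1)
  expect_equal(functional_richness(space, c("s1", "s5", "s6")), 0.125)

  fr <- functional_richness(space, c("s1", "s2"))
  expect_true(is.na(fr))
  expect_equal(attr(fr, "reason"), "too_few")
  fr2 <- functional_richness(space, c("s1", "s5", "s2"))  # collinear
  expect_true(is.na(fr2))
  expect_equal(attr(fr2, "reason"), "degenerate")
})

test_that("functional richness is invariant to order and rotation", {
  set.seed(43)
  P <- matrix(rnorm(30), 15, 2, dimnames = list(paste0("s", 1:15), NULL))
  space <- functional_space(P)
  sub <- c("s2", "s5", "s9", "s14")
  f1 <- functional_richness(space, sub)
  f2 <- functional_richness(space, rev(sub))
  expect_equal(f1, f2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  space_rot <- functional_space(P %*% R)
  expect_equal(functional_richness(space_rot, sub), f1, tolerance = 1e-9)
})

test_that("functional beta partition matches the square fixtures", {
  pts <- rbind(cbind(c(0, 0, 2, 2), c(0, 2, 0, 2)),
               cbind(c(1, 1, 3, 3), c(1, 3, 1, 3)),
               cbind(c(0.5, 0.5, 1.2, 1.2), c(0.5, 1.2, 0.5, 1.2)))
  rownames(pts) <- paste0("s", 1:12)
  space <- functional_space(pts)
  fb <- functional_beta_pair(space, paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(fb$turnover, 0.75, tolerance = 1e-9)  # a=1, b=3, c=3
  expect_equal(fb$sor, 6 / 8, tolerance = 1e-9)
  expect_equal(fb$sor, fb$turnover + fb$nestedness, tolerance = 1e-9)

  nested <- functional_beta_pair(space, paste0("s", 1:4), paste0("s", 9:12))
  expect_equal(nested$turnover, 0, tolerance = 1e-9)
  expect_gt(nested$nestedness, 0)

  same <- functional_beta_pair(space, paste0("s", 1:4), paste0("s", 1:4))
  expect_equal(same$sor, 0, tolerance = 1e-9)
  expect_equal(same$turnover, 0, tolerance = 1e-9)
})

test_that("shared volume is bounded by both hull volumes", {
  set.seed(47)
  P <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30), NULL))
  space <- functional_space(P)
  for (i in 1:8) {
    sa <- sample(rownames(P), 8)
    sb <- sample(rownames(P), 8)
    fb <- functional_beta_pair(space, sa, sb)
    if (length(fb) == 1L && is.na(fb)) next
    expect_lte(fb$v_shared, min(fb$v_a, fb$v_b) + 1e-9)
    expect_equal(fb$sor, fb$turnover + fb$nestedness, tolerance = 1e-9)
  }
})

test_that("mean functional turnover averages pairwise turnover", {
  # identical cells: all zeros
  P <- rbind(cbind(c(0, 0, 2, 2), c(0, 2, 0, 2)), c(1, 1))
  rownames(P) <- paste0("s", 1:5)
  space <- functional_space(P)
  occ <- matrix(1L, 3, 5, dimnames = list(paste0("c", 1:3), paste0("s", 1:5)))
  mt <- mean_functional_turnover(occ, space)
  expect_equal(unname(mt), rep(0, 3), ignore_attr = TRUE)

  # three cells with known pairwise turnovers
  pts <- rbind(cbind(c(0, 0, 2, 2), c(0, 2, 0, 2)),
               cbind(c(1, 1, 3, 3), c(1, 3, 1, 3)),
               cbind(c(0, 0, 2, 2), c(0, 2, 0, 2)) + 10)
  rownames(pts) <- paste0("s", 1:12)
  sp2 <- functional_space(pts)
  occ2 <- matrix(0L, 3, 12,
                 dimnames = list(paste0("c", 1:3), paste0("s", 1:12)))
  occ2[1, 1:4] <- 1L; occ2[2, 5:8] <- 1L; occ2[3, 9:12] <- 1L
  mt2 <- mean_functional_turnover(occ2, sp2)
  expect_equal(unname(mt2[1]), mean(c(0.75, 1)), tolerance = 1e-9)

  # degenerate cell excluded and reported
  occ3 <- rbind(occ2, c4 = c(1, 1, rep(0, 10)))
  mt3 <- mean_functional_turnover(occ3, sp2)
  expect_true(is.na(mt3["c4"]))
  expect_equal(attr(mt3, "excluded"), "c4")
})

test_that("a functionally divergent realm has the highest mean turnover", {
  w <- build_world(world_config(n_rows = 4L, n_cols = 5L,
                                realm_spans = c(2L, 2L, 1L),
                                species_per_realm = 12L, mixing = 0,
                                trait_rate = 1, seed = 61L))
  # push one realm into its own region of trait space
  shift <- w$realm_of_species == "realm3"
  traits <- w$traits
  traits$data$body_mass[shift] <- traits$data$body_mass[shift] * 60
  space <- build_functional_space(traits, m = 2L)
  mt <- mean_functional_turnover(w$occurrence, space)
  realm <- w$realm_of_cell[names(mt)]
  expect_gt(mean(mt[realm == "realm3"], na.rm = TRUE),
            mean(mt[realm != "realm3"], na.rm = TRUE))
})
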