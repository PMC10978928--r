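test_that("newick reading validates structure and labels", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 4L)
  expect_equal(sum(tr$edge.length), 6)

  tr1 <- read_newick("(A:1);")
  expect_equal(length(tr1$tip.label), 1L)

  expect_error(read_newick("((A:1,A:2):1);"), "duplicate tip labels")
  expect_error(read_newick("((A:1,B:1:1);"), "malformed")
})

test_that("branch sets follow the rooted convention", {
  tr <- fixture_tree4()
  expect_equal(assemblage_branch_set(tr, c("A", "B"))$total, 3)
  expect_equal(assemblage_branch_set(tr, tr$tip.label)$total, 6)
  expect_equal(assemblage_branch_set(tr, "A")$total, 2)
  expect_error(assemblage_branch_set(tr, character(0)), "empty")
  expect_error(assemblage_branch_set(tr, c("A", "zz")), "not in tree")
})

test_that("Faith's PD matches hand enumeration and is monotone", {
  tr <- fixture_tree4()
  expect_equal(faith_pd(tr, c("A", "B")), 3)
  expect_equal(faith_pd(tr, c("A", "C")), 4)
  expect_equal(faith_pd(tr, tr$tip.label), sum(tr$edge.length))

  set.seed(41)
  for (i in 1:20) {
    tree <- ape::rtree(10)
    s <- random_assemblage(tree$tip.label)
    extra <- random_assemblage(tree$tip.label)
    expect_gte(faith_pd(tree, union(s, extra)) + 1e-12, faith_pd(tree, s))
  }
})

test_that("pairwise phylobetadiversity matches the worked fixture", {
  tr <- fixture_tree4()
  p <- phylobeta_pair(tr, c("A", "B"), c("A", "C"))
  expect_equal(p$sim, 1 / 3)
  expect_equal(p$sor, 3 / 7)
  expect_equal(p$nes, 3 / 7 - 1 / 3)

  same <- phylobeta_pair(tr, c("A", "B"), c("B", "A"))
  expect_equal(same$sim, 0)
  expect_equal(same$sor, 0)

  disjoint <- phylobeta_pair(tr, c("A", "B"), c("C", "D"))
  expect_equal(disjoint$sim, 1)
  expect_equal(disjoint$a, 0)
})

test_that("random pairs agree with the brute-force edge-set oracle", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(4:12, 1L)
    tree <- ape::rtree(n)
    sa <- random_assemblage(tree$tip.label)
    sb <- random_assemblage(tree$tip.label)
    got <- phylobeta_pair(tree, sa, sb)
    want <- oracle_phylobeta(tree, sa, sb)
    expect_equal(got$sim, want$sim, tolerance = 1e-12)
    expect_equal(got$sor, want$sor, tolerance = 1e-12)
    expect_equal(got$sor, got$sim + got$nes, tolerance = 1e-12)
    # symmetry
    rev <- phylobeta_pair(tree, sb, sa)
    expect_equal(rev$sim, got$sim, tolerance = 1e-12)
    expect_equal(rev$sor, got$sor, tolerance = 1e-12)
  }
})

test_that("the all-pairs matrix equals per-pair computation", {
  tr <- fixture_tree4()
  occ <- rbind(c1 = c(A = 1, B = 1, C = 0, D = 0),
               c2 = c(A = 1, B = 0, C = 1, D = 0),
               c3 = c(A = 0, B = 0, C = 1, D = 1))
  pb <- phylobeta_matrix(tr, occ)
  sim <- as.matrix(pb$sim)
  expect_equal(sim["c1", "c2"], 1 / 3)
  expect_equal(sim["c1", "c3"], 1)
  expect_equal(sim["c2", "c3"], 1 / 3)
  expect_true(all(diag(sim) == 0))
  expect_equal(unname(pb$pd), c(3, 4, 3))

  set.seed(11)
  tree <- ape::rtree(9)
  occ <- matrix(rbinom(45, 1, 0.5), 5, 9,
                dimnames = list(paste0("c", 1:5), tree$tip.label))
  occ[rowSums(occ) == 0, 1] <- 1L
  pb <- phylobeta_matrix(tree, occ)
  for (i in 1:4) for (j in (i + 1):5) {
    want <- oracle_phylobeta(tree,
                             tree$tip.label[occ[i, ] == 1],
                             tree$tip.label[occ[j, ] == 1])
    expect_equal(as.matrix(pb$sim)[i, j], want$sim, tolerance = 1e-12)
    expect_equal(as.matrix(pb$nes)[i, j], want$nes, tolerance = 1e-12)
  }
})

test_that("empty cells are rejected unless explicitly dropped", {
  tr <- fixture_tree4()
  occ <- rbind(c1 = c(A = 1, B = 1, C = 0, D = 0),
               c2 = c(A = 0, B = 0, C = 0, D = 0),
               c3 = c(A = 0, B = 0, C = 1, D = 1))
  expect_error(phylobeta_matrix(tr, occ), "without species")
  expect_warning(pb <- phylobeta_matrix(tr, occ, drop_empty = TRUE),
                 "dropping")
  expect_equal(pb$cells, c("c1", "c3"))
  expect_equal(pb$dropped, "c2")
})

test_that("on a star tree with unit edges sim reduces to species Simpson", {
  star <- ape::read.tree(text = paste0(
    "(", paste0(letters[1:8], ":1", collapse = ","), ");"))
  set.seed(5)
  for (i in 1:25) {
    sa <- random_assemblage(star$tip.label)
    sb <- random_assemblage(star$tip.label)
    a <- length(intersect(sa, sb))
    b <- length(setdiff(sa, sb))
    c_ <- length(setdiff(sb, sa))
    got <- phylobeta_pair(star, sa, sb)
    expect_equal(got$sim, min(b, c_) / (a + min(b, c_)), tolerance = 1e-12)
  }
})

test_that("zero-length edges change no totals", {
  tr <- read_newick("((A:1,B:1):0,(C:1,D:1):1);")
  expect_equal(faith_pd(tr, c("A", "B")), 2)
  p <- phylobeta_pair(tr, c("A", "B"), c("C", "D"))
  expect_equal(p$sim, 1)  # still fully disjoint shared length
})

test_that("Faith's PD agrees with the picante implementation", {
  skip_if_not_installed("picante")
  set.seed(99)
  tree <- ape::rtree(15)
  occ <- matrix(rbinom(75, 1, 0.5), 5, 15,
                dimnames = list(paste0("c", 1:5), tree$tip.label))
  occ[rowSums(occ) == 0, 1] <- 1L
  ref <- picante::pd(occ, tree, include.root = TRUE)
  got <- vapply(1:5, function(i) {
    faith_pd(tree, colnames(occ)[occ[i, ] == 1])
  }, numeric(1))
  expect_equal(got, ref$PD, tolerance = 1e-9)
})
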