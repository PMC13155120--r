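test_that("neutral Hill number at q = 1 matches hand-computed values", {
  expect_equal(hill_neutral_q1(c(0.5, 0.5)), 2.0)
  expect_equal(hill_neutral_q1(c(1, 0)), 1.0)
  expect_equal(hill_neutral_q1(c(0.7, 0.2, 0.1)), exp(0.80181855),
               tolerance = 1e-7)  # exp of hand-computed Shannon entropy
  expect_error(hill_neutral_q1(c(0.5, -0.1)), "negative")
  expect_error(hill_neutral_q1(c(0, 0)), "zero")
})

test_that("neutral Hill is bounded by richness with equality iff uniform", {
  set.seed(31)
  for (i in 1:50) {
    s <- sample(2:20, 1)
    p <- rgamma(s, 1); p <- p / sum(p)
    h <- hill_neutral_q1(p)
    expect_lte(h, s + 1e-12)
    expect_gt(h, 1 - 1e-12)
  }
  expect_equal(hill_neutral_q1(rep(1 / 7, 7)), 7)
})

test_that("phylogenetic Hill reduces to neutral on star trees", {
  star2 <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(hill_phylo_q1(c(a = 0.5, b = 0.5), star2), 2.0)
  expect_equal(hill_phylo_q1(c(a = 1, b = 0), star2), 1.0)
  star5 <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  set.seed(41)
  for (i in 1:50) {
    p <- rgamma(5, 1); p <- p / sum(p); names(p) <- letters[1:5]
    expect_equal(hill_phylo_q1(p, star5), hill_neutral_q1(p),
                 tolerance = 1e-9)
  }
  expect_error(hill_phylo_q1(c(a = 0.5, z = 0.5), star2), "missing")
})

test_that("phylogenetic Hill matches a branch-enumeration oracle on a comb tree", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  p <- c(a = 0.5, b = 0.3, c = 0.2)
  # oracle: enumerate the four branches (a, b, their ancestor, c) by hand
  branches <- list(list(len = 1, a = 0.5),        # tip a
                   list(len = 1, a = 0.3),        # tip b
                   list(len = 1, a = 0.8),        # (a,b) ancestor
                   list(len = 2, a = 0.2))        # tip c
  tbar <- sum(vapply(branches, function(b) b$len * b$a, numeric(1)))
  expected <- exp(-sum(vapply(branches, function(b)
    (b$len / tbar) * b$a * log(b$a), numeric(1))))
  expect_equal(hill_phylo_q1(p, tree), expected, tolerance = 1e-12)
})

test_that("functional Hill handles distinct, identical and rescaled traits", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(hill_functional_q1(c(0.5, 0.5), d2), 4.0)
  expect_error(hill_functional_q1(1, matrix(0, 1, 1)), "degenerate")
  # rescaling d leaves the result unchanged (d/Q invariance)
  set.seed(53)
  x <- matrix(runif(12), 4, 3)
  d <- as.matrix(dist(x))
  p <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(hill_functional_q1(p, d * 7.3), hill_functional_q1(p, d),
               tolerance = 1e-12)
  expect_error(hill_functional_q1(p, d[, 1:3]), "square")
  dasym <- d; dasym[1, 2] <- dasym[1, 2] + 1
  expect_error(hill_functional_q1(p, dasym), "symmetric")
})

test_that("classical-scaling PCoA reconstructs Euclidean geometry", {
  # three collinear points: one positive eigenvalue, spacing recovered
  pts <- matrix(c(0, 1, 3), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  res <- pcoa(dist(pts), k = 3)
  expect_equal(sum(res$eig > 1e-9), 1L)
  expect_equal(as.matrix(dist(res$points)), as.matrix(dist(pts)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # distances from a trait matrix are reproduced when eigenvalues are >= 0
  set.seed(61)
  gifts <- matrix(runif(5 * 8), 5, 8,
                  dimnames = list(paste0("g", 1:5), paste0("B", 1:8)))
  d <- dist(gifts)
  res2 <- pcoa(d, k = 4)
  expect_equal(as.matrix(dist(res2$points)), as.matrix(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  # agrees with stats::cmdscale up to sign of axes
  cmd <- stats::cmdscale(d, k = 4, eig = TRUE)
  expect_equal(abs(res2$points), abs(cmd$points), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(res2$eig[1:4], cmd$eig[1:4], tolerance = 1e-8)
  # identical rows collapse to coincident coordinates
  same <- matrix(1, 3, 3)
  res3 <- pcoa(dist(same))
  expect_equal(ncol(res3$points), 0L)
})

test_that("diversity table computes all three components and skips empty samples", {
  set.seed(71)
  tree <- simulate_tree(6, seed = 3)
  rel <- matrix(rgamma(18, 1), 6, 3,
                dimnames = list(tree$tip.label, paste0("s", 1:3)))
  rel <- sweep(rel, 2, colSums(rel), "/")
  gifts <- matrix(runif(24), 6, 4,
                  dimnames = list(tree$tip.label, paste0("B", 1:4)))
  div <- diversity_table(rel, tree, gifts)
  expect_identical(names(div), c("sample", "neutral", "phylogenetic",
                                 "functional"))
  expect_equal(nrow(div), 3L)
  expect_true(all(div$neutral > 1 & div$neutral <= 6))
  rel[, 2] <- 0
  expect_warning(div2 <- diversity_table(rel, tree, gifts), "empty")
  expect_equal(nrow(div2), 2L)
})
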