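test_that("percentile bootstrap CI brackets the mean, honours level and seed", {
  set.seed(81)
  x <- rnorm(30, 5)
  ci <- bootstrap_ci_mean(x, n_boot = 2000, seed = 4)
  expect_lte(ci[["lower"]], ci[["mean"]])
  expect_gte(ci[["upper"]], ci[["mean"]])
  expect_equal(ci[["mean"]], mean(x))
  # constant data give a degenerate interval
  expect_equal(unname(bootstrap_ci_mean(rep(2.5, 10), 100, seed = 1)),
               c(2.5, 2.5, 2.5))
  # widening the level widens the interval monotonically
  ci90 <- bootstrap_ci_mean(x, 2000, level = 0.90, seed = 4)
  ci99 <- bootstrap_ci_mean(x, 2000, level = 0.99, seed = 4)
  expect_lte(ci99[["lower"]], ci90[["lower"]])
  expect_gte(ci99[["upper"]], ci90[["upper"]])
  # bit-identical reproducibility without touching the caller's stream
  expect_identical(bootstrap_ci_mean(x, 500, seed = 9),
                   bootstrap_ci_mean(x, 500, seed = 9))
})

test_that("taxon response classifies planted, null and deterministic signals", {
  # exactly proportional, zero noise: full support
  days <- rep(c(7, 21, 35), each = 5)
  r0 <- taxon_response(2 * days, days, n_boot = 200, seed = 1)
  expect_equal(r0$support, 1.0)
  expect_identical(r0$direction, "increase")
  # planted positive slope at twice the noise sd is found
  set.seed(91)
  d60 <- rep(c(7, 21, 35), each = 20)
  # slope 0.05/day over sd(day) ~ 11.7 days is ~2x the noise sd of 0.3
  y <- exp(0.05 * d60 + rnorm(60, 0, 0.3))
  r1 <- taxon_response(y, d60, n_boot = 300, seed = 2)
  expect_identical(r1$direction, "increase")
  expect_gt(r1$slope, 0)
  # input guards
  expect_error(taxon_response(y, rep(1, 60)), "constant")
  expect_error(taxon_response(y[1:5], d60[1:5]), "at least 8")
})

test_that("support is invariant to affine rescaling of the predictor", {
  set.seed(101)
  x <- runif(40, 0, 30)
  y <- rlnorm(40, 0.02 * x, 0.4)
  a <- taxon_response(y, x, n_boot = 300, seed = 7)
  b <- taxon_response(y, 5 + 0.1 * x, n_boot = 300, seed = 7)
  expect_identical(a$support, b$support)
  expect_identical(a$direction, b$direction)
  # x -> 5 + 0.1 x divides the fitted slope by 0.1
  expect_equal(b$slope, a$slope / 0.1, tolerance = 1e-8)
})

test_that("pure-noise taxa are mostly unclassified at the 0.9 support level", {
  set.seed(111)
  d60 <- rep(c(7, 21, 35), each = 20)
  dirs <- vapply(1:150, function(i) {
    taxon_response(rlnorm(60), d60, n_boot = 200, seed = 1000 + i)$direction
  }, character(1))
  # sign support >= 0.9 corresponds to |t| >= ~1.28, so the null rate of a
  # direction call is ~20% split between the signs
  expect_gte(mean(dirs == "none"), 0.70)
  expect_lte(mean(dirs == "increase"), 0.18)
})

test_that("community classification reports direction fractions", {
  expect_equal(unname(classify_community(rep("increase", 4))), c(1, 0, 0))
  expect_equal(unname(classify_community(rep("none", 3))), c(0, 0, 1))
  fr <- classify_community(c("increase", "decrease", "none", "increase"))
  expect_equal(sum(fr), 1)
  expect_equal(fr[["increase"]], 0.5)
  expect_error(classify_community(character(0)), "no responses")
  expect_error(classify_community("sideways"), "unknown direction")
})

test_that("MCI-response correlation recovers planted dependence and nulls", {
  m <- seq(0.1, 0.9, length.out = 20)
  res <- mci_response_correlation(m, -m, seed = 3)
  expect_equal(res$r, -1)
  expect_lt(res$p_value, 0.01)
  # planted r = -0.6 at n = 150 is detected
  set.seed(121)
  z <- rnorm(150)
  slopes <- -0.6 * z + sqrt(1 - 0.36) * rnorm(150)
  got <- mci_response_correlation(z, slopes, n_perm = 999, seed = 5)
  expect_lt(got$r, 0)
  expect_lt(got$p_value, 0.01)
  # independent vectors rarely show |r| > 0.3
  hits <- 0L
  for (i in 1:40) {
    set.seed(200 + i)
    r <- mci_response_correlation(rnorm(150), rnorm(150), n_perm = 99,
                                  seed = i)$r
    if (abs(r) < 0.3) hits <- hits + 1L
  }
  expect_gte(hits, 38L)
  expect_error(mci_response_correlation(rep(1, 10), rnorm(10)),
               "zero variance")
})

test_that("Moran's I agrees with the ape oracle and centres on its null", {
  set.seed(131)
  x <- rnorm(12)
  w <- matrix(rbinom(144, 1, 0.3), 12, 12)
  w <- (w + t(w) > 0) * 1; diag(w) <- 0
  # ape row-normalizes its weight matrix; feed the normalized form to ours
  ours <- magifts:::moran_i(x, w / rowSums(w))
  oracle <- ape::Moran.I(x, w, scaled = FALSE)
  expect_equal(ours, oracle$observed, tolerance = 1e-12)
  expect_equal(-1 / (12 - 1), oracle$expected)
})

test_that("phylogenetic correlogram finds signal under Brownian motion", {
  short_pos <- 0L
  for (s in 1:10) {
    tree <- simulate_tree(40, seed = 300 + s)
    set.seed(400 + s)
    x <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    cg <- phylo_correlogram(setNames(as.numeric(x), names(x)), tree,
                            n_classes = 5)
    if (cg$moran_i[1] > 0) short_pos <- short_pos + 1L
  }
  expect_gte(short_pos, 9L)
  # permuted responses centre on the Moran null expectation -1/(n-1)
  tree <- simulate_tree(40, seed = 5)
  set.seed(141)
  vals <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  perm_means <- replicate(30, {
    v <- setNames(sample(as.numeric(vals)), names(vals))
    mean(phylo_correlogram(v, tree, n_classes = 5)$moran_i)
  })
  expect_equal(mean(perm_means), -1 / 39, tolerance = 0.02)
  # two-tip tree: a single class defined from the one pair
  t2 <- ape::read.tree(text = "(a:1,b:1);")
  cg2 <- phylo_correlogram(c(a = 1, b = -1), t2, n_classes = 1)
  expect_equal(nrow(cg2), 1L)
  expect_equal(cg2$n_pairs, 1)
  expect_error(phylo_correlogram(c(a = 1, b = -1), t2, n_classes = 5),
               "exceeds")
})

test_that("bootstrap group comparison applies the non-overlap evidence rule", {
  same <- group_compare_bootstrap(rep(c(5, 5, 5), 2),
                                  rep(c("a", "b"), each = 3),
                                  n_boot = 500, seed = 1)
  expect_identical(same$verdicts$verdict, "overlapping")
  expect_equal(same$groups$lower, c(5, 5))
  # well-separated Gaussians are called distinct across seeds
  distinct <- 0L
  for (s in 1:10) {
    set.seed(500 + s)
    v <- c(rnorm(30, 0), rnorm(30, 3))
    g <- rep(c("lo", "hi"), each = 30)
    cmp <- group_compare_bootstrap(v, g, n_boot = 1000, seed = s)
    if (all(cmp$verdicts$verdict == "distinct")) distinct <- distinct + 1L
  }
  expect_gte(distinct, 10L)
  # CIs contain the group mean; singletons are rejected
  set.seed(151)
  v <- rnorm(20); g <- rep(c("a", "b"), 10)
  cmp <- group_compare_bootstrap(v, g, n_boot = 1000, seed = 2)
  expect_true(all(cmp$groups$lower <= cmp$groups$mean &
                    cmp$groups$mean <= cmp$groups$upper))
  expect_error(group_compare_bootstrap(1:5, c("a", "a", "a", "a", "b")),
               "singleton")
  expect_identical(group_compare_bootstrap(v, g, 500, seed = 3),
                   group_compare_bootstrap(v, g, 500, seed = 3))
})
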