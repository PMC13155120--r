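test_that("generated trees have the requested shape and are reproducible", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  expect_true(ape::is.rooted(t2))
  t100 <- simulate_tree(100, seed = 1)
  expect_equal(length(t100$tip.label), 100L)
  expect_equal(t100$Nnode, 99L)
  expect_identical(ape::write.tree(simulate_tree(20, seed = 9)),
                   ape::write.tree(simulate_tree(20, seed = 9)))
  expect_false(identical(ape::write.tree(simulate_tree(20, seed = 9)),
                         ape::write.tree(simulate_tree(20, seed = 10))))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("the generated trait database is valid and anchors are present", {
  db <- simulate_trait_db(40)
  expect_length(gift_codes(db), 40L)
  expect_identical(validate_trait_db(db), character(0))
  expect_true(all(c("B0101", "B0102", "B0103", "B0211", "B0401", "B0402",
                    "B0403", "B0701", "B0805", "D0509") %in%
                    gift_codes(db)))
  expect_length(gift_codes(simulate_trait_db(170)), 170L)
  expect_error(simulate_trait_db(10))
})

test_that("genome simulation couples genome length to metabolic capacity", {
  cfg <- scenario_config(n_taxa = 200)
  for (s in 1:3) {
    tree <- simulate_tree(200, seed = s)
    gen <- simulate_genomes(tree, cfg, seed = s)
    expect_true(all(gen$gifts >= 0 & gen$gifts <= 1))
    expect_gt(cor(gen$genome_length_bp, gen$mci), 0.5)
  }
})

test_that("planted genome-reduced guilds have the contracted gene content", {
  cfg <- small_config()
  tree <- simulate_tree(cfg$n_taxa, seed = 2)
  gen <- simulate_genomes(tree, cfg, seed = 2)
  db <- gen$db
  nacid_ids <- unlist(lapply(c("B0101", "B0102", "B0103"), function(code)
    unlist(db$elements[[code]]$steps, use.names = FALSE)))
  for (g in c(gen$reduced_a, gen$reduced_b))
    expect_length(intersect(gen$annotations[[g]], nacid_ids), 0L)
  for (g in setdiff(names(gen$annotations), c(gen$reduced_a, gen$reduced_b)))
    expect_gt(length(intersect(gen$annotations[[g]], nacid_ids)), 0L)
  # guild A carries its full signature pathways
  expect_true(all(gen$gifts[gen$reduced_a, c("B0211", "B0701", "B0805",
                                             "D0509")] == 1))
  # guild B carries thiamine but was not handed the lysine pathway
  expect_true(all(gen$gifts[gen$reduced_b, "B0701"] == 1))
})

test_that("count simulation hits the configured MCI-slope correlation", {
  cfg <- scenario_config()
  for (s in 1:3) {
    tree <- simulate_tree(cfg$n_taxa, seed = s)
    gen <- simulate_genomes(tree, cfg, seed = s)
    cs <- simulate_counts(gen, cfg, seed = s)
    expect_equal(cor(gen$mci, cs$truth$slopes), -0.6, tolerance = 0.15)
    ab <- cs$abundance
    expect_true(all(ab$breadth >= 0 & ab$breadth <= 1))
    expect_true(all(ab$breadth[ab$counts == 0] == 0))
    expect_true(all(ab$mapped_read_pairs <= ab$total_read_pairs))
    expect_equal(nrow(cs$metadata), ncol(ab$counts))
  }
})

test_that("weights respond to planted taxa and an optional diversity term", {
  cfg <- small_config()
  sc <- simulate_scenario(cfg, seed = 3)
  md <- sc$metadata
  expect_false(anyNA(md$body_weight_g))
  expect_length(sc$truth$positive_taxa, cfg$n_positive_assoc)
  expect_length(sc$truth$negative_taxa, cfg$n_negative_assoc)
  # with all effects off, day-35 weights are baseline plus noise
  cfg0 <- small_config(pos_effect = 0, neg_effect = 0)
  sc0 <- simulate_scenario(cfg0, seed = 3)
  w35 <- sc0$metadata$body_weight_g[sc0$metadata$day == 35]
  expect_equal(mean(w35), 2200,
               tolerance = 4 * 150 / sqrt(length(w35)) / 2200)
  expect_lt(sd(w35), 1.5 * 150)
  # a planted negative diversity effect shows up as a negative regression
  # slope of weight on neutral diversity at day 35
  for (s in 1:3) {
    scd <- simulate_scenario(small_config(pos_effect = 0, neg_effect = 0,
                                          diversity_effect = 2), seed = s)
    rel <- suppressWarnings(relative_abundance(scd$abundance))
    d35 <- scd$metadata$day == 35
    h <- apply(rel[, d35], 2, hill_neutral_q1)
    fit <- coef(lm(scd$metadata$body_weight_g[d35] ~ h))[2]
    expect_lt(fit, 0)
  }
})

test_that("transcript simulation plants the two expression guilds", {
  cfg <- small_config()
  sc <- simulate_scenario(cfg, seed = 4)
  db <- sc$genomes$db
  flags <- detect_genome_reduced(sc$transcripts, db,
                                 genomes = names(sc$genomes$annotations))
  planted <- c(sc$truth$reduced_a, sc$truth$reduced_b)
  expect_true(all(flags$genome_reduced[flags$genome %in% planted]))
  expect_false(any(flags$genome_reduced[!(flags$genome %in% planted) &
                                          !flags$no_data]))
  em <- expression_by_gift(sc$transcripts, db, normalized = FALSE)
  expect_true(all(em[sc$truth$reduced_b, "B0211"] == 0))
  expect_true(all(rowSums(em[sc$truth$reduced_a,
                             c("B0401", "B0402", "B0403")]) > 0))
})

test_that("the full bundle is deterministic under (config, seed)", {
  cfg <- small_config()
  a <- simulate_scenario(cfg, seed = 11)
  b <- simulate_scenario(cfg, seed = 11)
  expect_identical(a$abundance$counts, b$abundance$counts)
  expect_identical(a$metadata$body_weight_g, b$metadata$body_weight_g)
  expect_identical(a$transcripts$counts, b$transcripts$counts)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  c <- simulate_scenario(cfg, seed = 12)
  expect_false(identical(a$abundance$counts, c$abundance$counts))
})

test_that("generated inputs satisfy the consuming validators", {
  sc <- simulate_scenario(small_config(), seed = 6)
  expect_identical(validate_trait_db(sc$genomes$db), character(0))
  expect_s3_class(sc$abundance, "abundance_table")     # constructor validated
  expect_s3_class(sc$transcripts, "transcript_table")
  rel <- suppressWarnings(relative_abundance(sc$abundance))
  ok <- !is.na(colSums(rel))
  expect_true(all(abs(colSums(rel[, ok]) - 1) < 1e-9))
})
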