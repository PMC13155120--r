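make_tt <- function(genes, counts) {
  transcript_table(genes, counts)
}

test_that("transcript normalization is TPM-style and scale invariant", {
  g1 <- data.frame(gene = "x", genome = "m1", identifier = "K1",
                   length_bp = 1500)
  c1 <- matrix(42, 1, 1, dimnames = list("x", "s1"))
  expect_equal(unname(normalize_transcripts(make_tt(g1, c1))[1, 1]), 1e6)
  g2 <- data.frame(gene = c("x", "y"), genome = "m1",
                   identifier = c("K1", "K2"), length_bp = c(1000, 2000))
  c2 <- matrix(c(30, 30), 2, 1, dimnames = list(c("x", "y"), "s1"))
  norm <- normalize_transcripts(make_tt(g2, c2))
  expect_equal(unname(norm[, 1]), c(2 / 3, 1 / 3) * 1e6)
  c2b <- c2 * 17
  expect_equal(normalize_transcripts(make_tt(g2, c2b)), norm)
  c2z <- cbind(c2, s2 = c(0, 0))
  expect_warning(nz <- normalize_transcripts(make_tt(g2, c2z)),
                 "zero-total")
  expect_true(all(is.na(nz[, "s2"])))
})

test_that("GIFT expression attributes genes to every matching element", {
  db <- tiny_db()
  genes <- data.frame(
    gene = c("a", "b", "c"),
    genome = c("m1", "m1", "m2"),
    identifier = c("K03147", "K00946", "K01478"),  # B0701 x2, D0509
    length_bp = c(1000, 1000, 1000))
  counts <- matrix(c(10, 5, 0), 3, 1,
                   dimnames = list(c("a", "b", "c"), "s1"))
  em <- expression_by_gift(make_tt(genes, counts), db, normalized = FALSE)
  expect_true(em["m1", "B0701"] > 0)
  expect_equal(em["m1", "B0211"], 0)
  expect_equal(em["m1", "D0509"], 0)
  expect_identical(unname(em["m2", ]), c(0, 0, 0))  # zero-count genome
  expect_equal(em["m1", "B0701"], 15)
})

test_that("an identifier shared by two elements contributes to both columns", {
  db <- trait_db(list(
    gift_definition("B0101", "one", list(list("K777"))),
    gift_definition("B0102", "two", list(list("K777"), list("K888")))))
  genes <- data.frame(gene = "g", genome = "m1", identifier = "K777",
                      length_bp = 1000)
  counts <- matrix(8, 1, 1, dimnames = list("g", "s1"))
  em <- expression_by_gift(make_tt(genes, counts), db, normalized = FALSE)
  expect_equal(unname(em["m1", c("B0101", "B0102")]), c(8, 8))
  # unmatched identifiers are ignored but counted
  genes2 <- rbind(genes, data.frame(gene = "h", genome = "m1",
                                    identifier = "K000", length_bp = 500))
  counts2 <- rbind(counts, h = 3)
  em2 <- expression_by_gift(make_tt(genes2, counts2), db,
                            normalized = FALSE)
  expect_equal(attr(em2, "n_unassigned_genes"), 1L)
  expect_equal(unname(em2["m1", "B0101"]), 8)
})

test_that("per-sample attribution is additive across samples", {
  db <- tiny_db()
  genes <- data.frame(gene = c("a", "b"), genome = "m1",
                      identifier = c("K03147", "K01478"),
                      length_bp = c(1000, 2000))
  counts <- matrix(c(6, 2, 4, 8), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  tt <- make_tt(genes, counts)
  per <- expression_by_gift(tt, db, pooling = "per_sample",
                            normalized = FALSE)
  pooled <- expression_by_gift(tt, db, pooling = "pooled",
                               normalized = FALSE)
  summed <- per$s1 + per$s2
  expect_equal(unname(summed), unname(pooled))
})

test_that("fullness mode scores pathways over expressed identifiers", {
  db <- tiny_db()
  genes <- data.frame(gene = c("a", "b"), genome = "m1",
                      identifier = c("K00928", "K00133"),
                      length_bp = c(1000, 1000))
  counts <- matrix(c(5, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  em <- expression_by_gift(make_tt(genes, counts), db, mode = "fullness")
  # only K00928 transcribed: step 1 of B0211 is half full, steps 2-3 empty
  expect_equal(em["m1", "B0211"], 0.5 / 3)
})

test_that("genome reduction is flagged on exact non-transcription", {
  db <- simulate_trait_db(20)
  ids <- lapply(c("B0101", "B0102", "B0103", "B0211"), function(code)
    unlist(db$elements[[code]]$steps, use.names = FALSE)[1])
  genes <- data.frame(gene = paste0("g", 1:4),
                      genome = c("m1", "m1", "m2", "m2"),
                      identifier = unlist(ids)[c(1, 2, 3, 4)],
                      length_bp = 1000)
  counts <- matrix(c(0, 0, 1, 5), 4, 1,
                   dimnames = list(genes$gene, "s1"))
  # m1: zero counts on B0101+B0102 genes, no B0103 gene -> reduced
  # m2: one B0103 transcript -> any transcription disqualifies
  flags <- detect_genome_reduced(make_tt(genes, counts), db,
                                 genomes = c("m1", "m2", "m3"))
  expect_identical(flags$genome_reduced, c(TRUE, FALSE, TRUE))
  expect_identical(flags$no_data, c(FALSE, FALSE, TRUE))
  db_small <- trait_db(list(gift_definition("B0901", "x",
                                            list(list("K1")))))
  expect_error(detect_genome_reduced(make_tt(genes, counts), db_small),
               "absent from the trait database")
})

test_that("Hellinger rows are unit-norm square-rooted proportions", {
  h <- hellinger(matrix(c(1, 3), 1, 2))
  expect_equal(unname(h[1, ]), c(0.5, sqrt(3) / 2))
  set.seed(161)
  m <- matrix(rpois(30, 4), 5, 6)
  m[1, ] <- m[1, ] + 1
  hs <- hellinger(m)
  expect_equal(unname(rowSums(hs[rowSums(m) > 0, , drop = FALSE]^2)),
               rep(1, sum(rowSums(m) > 0)))
})

test_that("expression ordination separates disjoint profiles and drops empty rows", {
  expr <- rbind(g1 = c(4, 4, 0, 0), g2 = c(4, 4, 0, 0),
                g3 = c(0, 0, 3, 3), g4 = c(0, 0, 0, 0))
  colnames(expr) <- paste0("B", 1:4)
  expect_warning(ord <- expression_ordination(expr), "all-zero")
  expect_identical(ord$excluded, "g4")
  # identical rows coincide; disjoint-support rows sit at Bray-Curtis 1
  expect_equal(ord$points["g1", ], ord$points["g2", ], tolerance = 1e-10)
  d <- vegan::vegdist(hellinger(expr[1:3, ]), method = "bray")
  expect_equal(as.matrix(d)["g1", "g3"], 1)
  expect_equal(as.matrix(d)["g1", "g2"], 0)
  suppressWarnings(
    expect_error(expression_ordination(expr[c(1, 4), ]), "at least 2"))
})
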