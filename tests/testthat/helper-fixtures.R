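# Shared fixtures and independent oracles, built in code.

# Small hand-built trait database covering joint clauses, alternative
# clauses and singleton steps.
tiny_db <- function() {
  trait_db(
    list(
      gift_definition("B0211", "lysine biosynthesis",
                      list(list(c("K00928", "K00133")),
                           list("K01714", "K00215"),
                           list("K00290"))),
      gift_definition("B0701", "thiamine biosynthesis",
                      list(list(c("K03147", "K00877")),
                           list("K00946"))),
      gift_definition("D0509", "arginine degradation",
                      list(list("K01478"),
                           list(c("K00611", "K01940"))))),
    c(B0211 = "Amino acid biosynthesis",
      B0701 = "Vitamin biosynthesis",
      D0509 = "Amino acid degradation"))
}

all_db_identifiers <- function(db) {
  unique(unlist(lapply(db$elements, function(el)
    unlist(el$steps, use.names = FALSE)), use.names = FALSE))
}

# Brute-force scoring oracle: explicit loops and counters, independent of the
# vectorised implementation it checks.
oracle_step_fullness <- function(clauses, present) {
  best <- 0
  for (cl in clauses) {
    found <- 0L
    for (id in cl) if (id %in% present) found <- found + 1L
    frac <- found / length(cl)
    if (frac > best) best <- frac
  }
  best
}

oracle_gift_score <- function(def, present) {
  total <- 0
  for (st in def$steps) total <- total + oracle_step_fullness(st, present)
  total / length(def$steps)
}

# TRUE iff every step has at least one clause fully present.
oracle_complete <- function(def, present) {
  for (st in def$steps) {
    ok <- FALSE
    for (cl in st) if (all(cl %in% present)) ok <- TRUE
    if (!ok) return(FALSE)
  }
  TRUE
}

# Minimal abundance table for normalization tests.
make_abundance <- function(counts, breadth = NULL, lengths = NULL,
                           total = NULL, mapped = NULL) {
  if (is.null(breadth)) breadth <- (counts > 0) * 1
  if (is.null(lengths))
    lengths <- setNames(rep(2e6, nrow(counts)), rownames(counts))
  if (is.null(mapped)) mapped <- colSums(counts)
  if (is.null(total)) total <- pmax(mapped, 1) * 2
  abundance_table(counts, breadth, lengths,
                  setNames(total, colnames(counts)),
                  setNames(mapped, colnames(counts)))
}

# Small default scenario used by the slower integration tests.
small_config <- function(...) {
  scenario_config(n_taxa = 40, n_samples_per_day = 12, n_gifts = 20,
                  n_reduced_a = 3, n_reduced_b = 3, ...)
}
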