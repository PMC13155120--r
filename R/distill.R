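#' Fullness of one pathway step given observed identifiers
#'
#' A step is scored as the best of its alternative clauses, each clause as the
#' fraction of its jointly-required identifiers observed in the genome. For
#' the common two-identifier clause this reduces to the full / half / empty
#' rule: 1 when both identifiers are present, 0.5 when one is, 0 when none.
#'
#' @param step a step as stored in a [gift_definition()]: a list of clauses,
#'   each a character vector of identifiers.
#' @param present character vector (or set) of identifiers observed in the
#'   genome.
#' @return fullness in `[0, 1]`.
#' @examples
#' step <- list(c("K00928", "K00133"))
#' step_fullness(step, c("K00928"))            # 0.5
#' step_fullness(list("K01714", "K00215"), "K00215")  # alternatives: 1
#' @export
step_fullness <- function(step, present) {
  if (!is.list(step)) step <- list(step)
  if (length(step) == 0L) stop("step has no clauses")
  max(vapply(step, function(cl) mean(cl %in% present), numeric(1)))
}

#' GIFT score of a pathway for one genome
#'
#' The genome-inferred functional trait (GIFT) value: the arithmetic mean of
#' [step_fullness()] over the pathway's steps. 0 means none of the pathway's
#' genes are present, 1 means every step is fully covered.
#'
#' @param def a [gift_definition()].
#' @param present character vector of identifiers observed in the genome.
#' @return fullness in `[0, 1]`.
#' @export
gift_score <- function(def, present) {
  stopifnot(inherits(def, "gift_definition"))
  mean(vapply(def$steps, step_fullness, numeric(1), present = present))
}

#' Build per-genome identifier sets from a gene annotation table
#'
#' Collapses a long annotation table (one row per gene-identifier pair, the
#' shape of a DRAM-style `annotations.tsv` after melting) into one identifier
#' set per genome.
#'
#' @param annotations data frame with columns `genome` and `identifier`
#'   (a `gene` column, if present, is ignored for scoring).
#' @return named list: genome id -> character vector of distinct identifiers.
#' @export
annotation_sets <- function(annotations) {
  stopifnot(is.data.frame(annotations),
            all(c("genome", "identifier") %in% names(annotations)))
  lapply(split(as.character(annotations$identifier),
               as.character(annotations$genome)), unique)
}

#' Distill an annotated genome catalogue into a GIFT matrix
#'
#' @param annotations either a named list (genome id -> character vector of
#'   identifiers, as from [annotation_sets()]) or a long data frame with
#'   columns `genome`, `identifier`.
#' @param db a [trait_db()].
#' @return numeric matrix, genomes x GIFT elements, values in `[0, 1]`;
#'   one column per database element, one row per genome (an unannotated
#'   genome yields an all-zero row).
#' @export
distill_catalogue <- function(annotations, db) {
  stopifnot(inherits(db, "trait_db"))
  if (is.data.frame(annotations)) annotations <- annotation_sets(annotations)
  if (is.null(names(annotations)) || any(!nzchar(names(annotations))))
    stop("annotations must be named by genome id")
  if (anyDuplicated(names(annotations)))
    stop("duplicate genome id(s): ",
         paste(unique(names(annotations)[duplicated(names(annotations))]),
               collapse = ", "))
  codes <- gift_codes(db)
  out <- matrix(0, nrow = length(annotations), ncol = length(codes),
                dimnames = list(names(annotations), codes))
  for (i in seq_along(annotations)) {
    present <- unique(as.character(annotations[[i]]))
    out[i, ] <- vapply(db$elements, gift_score, numeric(1), present = present)
  }
  out
}

#' Metabolic Capacity Index of a genome
#'
#' The unweighted arithmetic mean of a genome's GIFT values; a scalar summary
#' of metabolic versatility in `[0, 1]` (generalists high, genome-reduced
#' specialists low). All elements enter with equal weight, with no
#' hierarchy weighting.
#'
#' @param gift_row numeric vector of GIFT values in `[0, 1]`.
#' @return scalar MCI in `[0, 1]`.
#' @export
mci <- function(gift_row) {
  if (length(gift_row) == 0L) stop("empty GIFT vector")
  if (anyNA(gift_row)) stop("GIFT vector contains NA")
  if (any(gift_row < 0 | gift_row > 1))
    stop("GIFT values must lie in [0, 1]")
  mean(gift_row)
}

#' Classify genomes into metabolic-capacity classes
#'
#' Thresholds follow the field's convention: low below 0.15, high above
#' 0.30, medium in the closed interval between them (so 0.15 and 0.30 are
#' both "medium"); the three classes partition `[0, 1]`.
#'
#' @param mci_value numeric vector of MCI values in `[0, 1]`.
#' @param low,high class boundaries.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
classify_capacity <- function(mci_value, low = 0.15, high = 0.30) {
  if (anyNA(mci_value) || any(mci_value < 0 | mci_value > 1))
    stop("MCI values must lie in [0, 1]")
  out <- ifelse(mci_value < low, "low",
                ifelse(mci_value > high, "high", "medium"))
  factor(out, levels = c("low", "medium", "high"))
}

#' Per-genome MCI table
#'
#' Convenience wrapper producing the genome-level summary used downstream:
#' MCI and capacity class per genome.
#'
#' @param gifts GIFT matrix from [distill_catalogue()].
#' @inheritParams classify_capacity
#' @return data frame with columns `genome`, `mci`, `capacity_class`.
#' @export
mci_table <- function(gifts, low = 0.15, high = 0.30) {
  stop_if_not_matrix_like(gifts, "GIFT matrix")
  m <- apply(gifts, 1L, mci)
  data.frame(genome = rownames(gifts), mci = unname(m),
             capacity_class = classify_capacity(unname(m), low, high),
             stringsAsFactors = FALSE)
}

#' Merge GIFT elements into functional categories
#'
#' Category value per genome = mean of the member elements' GIFT values, so
#' category scores stay in `[0, 1]`.
#'
#' @param gifts GIFT matrix from [distill_catalogue()].
#' @param db the [trait_db()] whose category map defines the merge.
#' @return numeric matrix, genomes x categories.
#' @export
aggregate_categories <- function(gifts, db) {
  stop_if_not_matrix_like(gifts, "GIFT matrix")
  cats <- gift_categories(db)
  missing <- setdiff(colnames(gifts), names(cats))
  if (length(missing))
    stop("GIFT column(s) without a category: ",
         paste(missing, collapse = ", "))
  cats <- cats[colnames(gifts)]
  labels <- sort(unique(unname(cats)))
  out <- vapply(labels, function(lb)
    rowMeans(gifts[, cats == lb, drop = FALSE]), numeric(nrow(gifts)))
  out <- matrix(out, nrow = nrow(gifts),
                dimnames = list(rownames(gifts), labels))
  out
}
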