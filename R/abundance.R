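#' Assemble a MAG x sample abundance table
#'
#' Bundles the read-mapping outputs consumed by the normalization stage:
#' per-cell read-pair counts, per-cell breadth of genome coverage, genome
#' lengths, and per-sample total and catalogue-mapped read-pair counts.
#'
#' @param counts MAG x sample matrix of non-negative read-pair counts.
#' @param breadth MAG x sample matrix of breadth of coverage in `[0, 1]`
#'   (fraction of genome positions covered by at least one read).
#' @param genome_length_bp named numeric vector, one length (bp) per MAG.
#' @param total_read_pairs named numeric vector, one total per sample.
#' @param mapped_read_pairs named numeric vector, reads mapped to the MAG
#'   catalogue per sample; defaults to `colSums(counts)`.
#' @return object of class `abundance_table`.
#' @export
abundance_table <- function(counts, breadth, genome_length_bp,
                            total_read_pairs,
                            mapped_read_pairs = colSums(counts)) {
  stop_if_not_matrix_like(counts, "counts")
  stop_if_not_matrix_like(breadth, "breadth")
  if (!identical(dim(counts), dim(breadth)) ||
      !identical(dimnames(counts), dimnames(breadth)))
    stop("counts and breadth must share dimensions and dimnames")
  if (any(counts < 0)) stop("negative counts")
  if (any(breadth < 0 | breadth > 1)) stop("breadth must lie in [0, 1]")
  genome_length_bp <- genome_length_bp[rownames(counts)]
  if (anyNA(genome_length_bp) || any(genome_length_bp <= 0))
    stop("every MAG needs a positive genome length")
  total_read_pairs <- total_read_pairs[colnames(counts)]
  mapped_read_pairs <- mapped_read_pairs[colnames(counts)]
  if (anyNA(total_read_pairs) || any(total_read_pairs <= 0))
    stop("every sample needs a positive total read-pair count")
  if (anyNA(mapped_read_pairs) || any(mapped_read_pairs < 0))
    stop("every sample needs a non-negative mapped read-pair count")
  if (any(mapped_read_pairs > total_read_pairs))
    stop("mapped read pairs exceed total read pairs in sample(s): ",
         paste(colnames(counts)[mapped_read_pairs > total_read_pairs],
               collapse = ", "))
  structure(list(counts = counts, breadth = breadth,
                 genome_length_bp = genome_length_bp,
                 total_read_pairs = total_read_pairs,
                 mapped_read_pairs = mapped_read_pairs),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table:", nrow(x$counts), "MAGs x", ncol(x$counts),
      "samples\n")
  cat("Median sample depth:", format(stats::median(colSums(x$counts)),
                                     big.mark = ","), "read pairs\n")
  invisible(x)
}

#' Remove low-coverage read-mapping counts
#'
#' Cell-wise filter: a MAG's counts in a sample are set to zero when its
#' breadth of coverage in that sample is strictly below the threshold
#' (default 30% of genome positions), discarding spurious mappings to absent
#' genomes. Everything else is unchanged.
#'
#' @param table an [abundance_table()].
#' @param threshold breadth threshold in `(0, 1]`; cells with
#'   `breadth < threshold` are zeroed.
#' @return a filtered `abundance_table`.
#' @export
filter_by_coverage <- function(table, threshold = 0.30) {
  stopifnot(inherits(table, "abundance_table"))
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  table$counts[table$breadth < threshold] <- 0
  table$mapped_read_pairs <- colSums(table$counts)
  table
}

#' Percentage of reads mapped to the MAG catalogue
#'
#' Per sample: retained read-pair counts summed over MAGs, divided by the
#' sample's total read pairs, times 100.
#'
#' @param table an [abundance_table()] (typically after
#'   [filter_by_coverage()]).
#' @return named numeric vector of percentages per sample.
#' @export
percent_mapped <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  100 * colSums(table$counts) / table$total_read_pairs
}

#' RPMM abundance: reads per million bases of genome, per million mapped reads
#'
#' `RPMM[i, j] = counts[i, j] / (genome_length_bp[i] / 1e6) /
#' (mapped_read_pairs[j] / 1e6)` — counts corrected for genome length and for
#' per-sample sequencing effort, so RPMM is invariant to jointly scaling a
#' sample's counts and its mapped total.
#'
#' @param table an [abundance_table()].
#' @return MAG x sample matrix of RPMM values; samples with a zero mapped
#'   total are emitted as `NA` columns with a warning.
#' @export
rpmm <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  mapped <- table$mapped_read_pairs
  out <- sweep(table$counts, 1L, table$genome_length_bp / 1e6, "/")
  out <- sweep(out, 2L, mapped / 1e6, "/")
  empty <- mapped == 0
  if (any(empty)) {
    warning("sample(s) with no mapped reads emitted as NA: ",
            paste(colnames(out)[empty], collapse = ", "))
    out[, empty] <- NA_real_
  }
  out
}

#' Length-standardized relative abundances
#'
#' Counts are standardized by MAG genome length and renormalized so every
#' sample column sums to one over the retained MAGs.
#'
#' @param table an [abundance_table()].
#' @return MAG x sample matrix of proportions; all-zero samples are emitted
#'   as `NA` columns with a warning.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  std <- sweep(table$counts, 1L, table$genome_length_bp, "/")
  tot <- colSums(std)
  empty <- tot == 0
  if (any(empty)) {
    warning("empty sample(s) emitted as NA: ",
            paste(colnames(std)[empty], collapse = ", "))
    tot[empty] <- NA_real_
  }
  sweep(std, 2L, tot, "/")
}

#' Community-weighted GIFT profile and community MCI per sample
#'
#' Each sample's community-weighted value of a GIFT element is the
#' relative-abundance-weighted sum of the member genomes' values
#' (`sum_i p_i * gift[i, g]`); the community MCI is the mean of those
#' community-weighted values over elements — the abundance-weighted analogue
#' of the per-genome MCI, and always a convex combination of member MCIs.
#'
#' @param rel MAG x sample relative-abundance matrix from
#'   [relative_abundance()] (columns summing to 1).
#' @param gifts GIFT matrix from [distill_catalogue()]; rows must cover the
#'   MAGs of `rel`.
#' @return object of class `community_profile`: list with `cw_gifts`
#'   (sample x GIFT matrix) and `community_mci` (named vector per sample).
#' @export
community_weighted_gifts <- function(rel, gifts) {
  stop_if_not_matrix_like(rel, "relative abundance")
  stop_if_not_matrix_like(gifts, "GIFT matrix")
  missing <- setdiff(rownames(rel), rownames(gifts))
  if (length(missing))
    stop("MAG(s) missing from the GIFT matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  keep <- !is.na(colSums(rel))
  if (!all(keep))
    warning("dropping empty sample(s): ",
            paste(colnames(rel)[!keep], collapse = ", "))
  rel <- rel[, keep, drop = FALSE]
  bad <- abs(colSums(rel) - 1) > 1e-9
  if (any(bad))
    stop("sample column(s) do not sum to 1: ",
         paste(colnames(rel)[bad], collapse = ", "))
  cw <- t(rel) %*% gifts[rownames(rel), , drop = FALSE]
  structure(list(cw_gifts = cw, community_mci = rowMeans(cw)),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat("Community profile:", nrow(x$cw_gifts), "samples x",
      ncol(x$cw_gifts), "GIFTs\n")
  cat("Community MCI range:",
      paste(signif(range(x$community_mci), 4), collapse = " - "), "\n")
  invisible(x)
}
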