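# Metatranscriptomic profiling: gene counts -> per-MAG GIFT expression,
# genome-reduction detection, and expression ordination.

#' Assemble a gene-level transcript table
#'
#' @param genes data frame with columns `gene`, `genome`, `identifier`
#'   (one or more function identifiers per gene, `";"`-separated) and
#'   `length_bp` (> 0). Every gene maps to exactly one genome.
#' @param counts gene x sample matrix of non-negative transcript counts;
#'   row names must match `genes$gene`.
#' @return object of class `transcript_table`.
#' @export
transcript_table <- function(genes, counts) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "genome", "identifier", "length_bp") %in%
                  names(genes)))
  stop_if_not_matrix_like(counts, "transcript counts")
  if (any(counts < 0)) stop("negative transcript counts")
  if (anyDuplicated(genes$gene))
    stop("duplicate gene id(s): a gene maps to exactly one genome")
  if (!setequal(genes$gene, rownames(counts)) ||
      nrow(genes) != nrow(counts))
    stop("genes and count rows must match one-to-one")
  if (any(genes$length_bp <= 0)) stop("gene lengths must be positive")
  genes <- genes[match(rownames(counts), genes$gene), , drop = FALSE]
  structure(list(genes = genes, counts = counts), class = "transcript_table")
}

#' @export
print.transcript_table <- function(x, ...) {
  cat("Transcript table:", nrow(x$counts), "genes,",
      length(unique(x$genes$genome)), "genomes,",
      ncol(x$counts), "samples\n")
  invisible(x)
}

#' Length- and depth-normalized transcript expression
#'
#' TPM-style contract: counts are divided by gene length in kb, then each
#' sample is rescaled to sum to one million — so values are invariant to
#' scaling a sample's counts.
#'
#' @param t a [transcript_table()].
#' @return gene x sample matrix of normalized expression; zero-total samples
#'   are emitted as `NA` columns with a warning.
#' @export
normalize_transcripts <- function(t) {
  stopifnot(inherits(t, "transcript_table"))
  rate <- sweep(t$counts, 1L, t$genes$length_bp / 1e3, "/")
  tot <- colSums(rate)
  empty <- tot == 0
  if (any(empty)) {
    warning("zero-total sample(s) emitted as NA: ",
            paste(colnames(rate)[empty], collapse = ", "))
    tot[empty] <- NA_real_
  }
  sweep(rate, 2L, tot / 1e6, "/")
}

split_identifiers <- function(ids) {
  strsplit(as.character(ids), ";", fixed = TRUE)
}

# code -> all identifiers appearing anywhere in the element's steps
db_identifier_sets <- function(db) {
  lapply(db$elements, function(el)
    unique(unlist(el$steps, use.names = FALSE)))
}

#' Per-MAG GIFT expression profiles from transcript counts
#'
#' Attribution contract: a gene contributes its (normalized) expression to
#' every GIFT element that lists one of the gene's identifiers; the element's
#' expression for a genome is the sum over that genome's contributing genes.
#' Genes whose identifiers match no element are ignored and counted in the
#' `n_unassigned_genes` attribute.
#'
#' The default is the abundance-weighted sum, giving graded expression
#' profiles; `mode = "fullness"` instead scores pathway fullness over the set
#' of expressed genes (count > 0), i.e. applies [gift_score()] to the
#' transcribed identifiers.
#'
#' @param t a [transcript_table()].
#' @param db a [trait_db()].
#' @param pooling `"pooled"` (default; samples summed before attribution,
#'   matching genome-level profiles) or `"per_sample"` (one matrix per
#'   sample, returned as a named list).
#' @param normalized use [normalize_transcripts()] values (default) or raw
#'   counts.
#' @param mode `"sum"` (default) or `"fullness"` (see above;
#'   forces pooled raw counts for the presence call).
#' @return genome x GIFT matrix (or list of them for `per_sample`), with
#'   attribute `n_unassigned_genes`.
#' @export
expression_by_gift <- function(t, db, pooling = c("pooled", "per_sample"),
                               normalized = TRUE,
                               mode = c("sum", "fullness")) {
  stopifnot(inherits(t, "transcript_table"), inherits(db, "trait_db"))
  pooling <- match.arg(pooling)
  mode <- match.arg(mode)
  codes <- gift_codes(db)
  genomes <- sort(unique(t$genes$genome))
  gene_ids <- split_identifiers(t$genes$identifier)
  if (mode == "fullness") {
    expressed <- rowSums(t$counts) > 0
    ann <- lapply(stats::setNames(genomes, genomes), function(g) {
      sel <- t$genes$genome == g & expressed
      unique(unlist(gene_ids[sel], use.names = FALSE))
    })
    out <- distill_catalogue(ann, db)
    attr(out, "n_unassigned_genes") <- NA_integer_
    return(out)
  }
  id_sets <- db_identifier_sets(db)
  all_db_ids <- unique(unlist(id_sets, use.names = FALSE))
  # gene -> element incidence (sparse via index lists)
  hits <- lapply(gene_ids, function(ids) {
    which(vapply(id_sets, function(s) any(ids %in% s), logical(1)))
  })
  unassigned <- sum(lengths(hits) == 0 |
                      !vapply(gene_ids, function(ids)
                        any(ids %in% all_db_ids), logical(1)))
  vals <- if (normalized) normalize_transcripts(t) else t$counts
  one_matrix <- function(v) {
    out <- matrix(0, length(genomes), length(codes),
                  dimnames = list(genomes, codes))
    for (i in seq_along(hits)) {
      k <- hits[[i]]
      if (!length(k)) next
      g <- t$genes$genome[i]
      out[g, k] <- out[g, k] + v[i]
    }
    attr(out, "n_unassigned_genes") <- unassigned
    out
  }
  if (pooling == "pooled") {
    one_matrix(rowSums(vals))
  } else {
    lapply(stats::setNames(colnames(vals), colnames(vals)),
           function(s) one_matrix(vals[, s]))
  }
}

#' Flag genome-reduced taxa by non-transcription of nucleic-acid biosynthesis
#'
#' A genome is flagged genome-reduced when its summed raw transcript count
#' over the nucleic-acid biosynthesis elements (by default B0101, B0102 and
#' B0103) is exactly zero — any transcription of any of the three
#' disqualifies. Raw counts are used on purpose: the criterion is lack of
#' transcription, so the flag is invariant to normalization.
#'
#' @param t a [transcript_table()].
#' @param db a [trait_db()]; must contain all `codes`.
#' @param codes GIFT codes whose non-transcription defines genome reduction.
#' @param genomes optional character vector of genomes to report; genomes
#'   absent from the transcript table are flagged with `no_data = TRUE`.
#' @return data frame with columns `genome`, `total_count`,
#'   `genome_reduced`, `no_data`.
#' @export
detect_genome_reduced <- function(t, db,
                                  codes = c("B0101", "B0102", "B0103"),
                                  genomes = NULL) {
  stopifnot(inherits(t, "transcript_table"), inherits(db, "trait_db"))
  missing <- setdiff(codes, gift_codes(db))
  if (length(missing))
    stop("code(s) absent from the trait database: ",
         paste(missing, collapse = ", "))
  expr_raw <- expression_by_gift(t, db, pooling = "pooled",
                                 normalized = FALSE)
  if (is.null(genomes)) genomes <- rownames(expr_raw)
  totals <- stats::setNames(rep(0, length(genomes)), genomes)
  no_data <- !(genomes %in% rownames(expr_raw))
  seen <- genomes[!no_data]
  totals[seen] <- rowSums(expr_raw[seen, codes, drop = FALSE])
  data.frame(genome = genomes, total_count = unname(totals),
             genome_reduced = unname(totals == 0),
             no_data = unname(no_data),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hellinger transform
#'
#' Square roots of row-wise proportions, so every nonzero row has unit sum of
#' squares; the standard pre-transform before Bray-Curtis ordination of
#' expression profiles.
#'
#' @param x non-negative matrix (rows = objects).
#' @return transformed matrix.
#' @export
hellinger <- function(x) {
  stopifnot(is.matrix(x), all(x >= 0))
  vegan::decostand(x, method = "hellinger")
}

#' Ordinate GIFT expression profiles
#'
#' Hellinger-transforms the expression matrix, computes Bray-Curtis
#' dissimilarities, and runs classical-scaling [pcoa()]. All-zero rows are
#' excluded with a warning.
#'
#' @param expr genome x GIFT expression matrix (e.g. from
#'   [expression_by_gift()]).
#' @param k number of ordination axes requested.
#' @return a [pcoa()] result with an added `excluded` element naming dropped
#'   rows.
#' @export
expression_ordination <- function(expr, k = 2) {
  stop_if_not_matrix_like(expr, "expression matrix")
  zero <- rowSums(expr) == 0
  excluded <- rownames(expr)[zero]
  if (any(zero))
    warning("excluding all-zero row(s): ", paste(excluded, collapse = ", "))
  expr <- expr[!zero, , drop = FALSE]
  if (nrow(expr) < 2L) stop("need at least 2 genomes with nonzero expression")
  d <- vegan::vegdist(hellinger(expr), method = "bray")
  out <- pcoa(d, k = k)
  out$excluded <- excluded
  out
}
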