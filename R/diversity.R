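# Hill-number diversities at q = 1 and classical-scaling ordination.
# All q = 1 forms use the analytic limit (exponentials of entropies), never a
# plug-in at q = 1.

check_props <- function(p) {
  if (anyNA(p)) stop("abundances contain NA")
  if (any(p < 0)) stop("negative abundances")
  s <- sum(p)
  if (s == 0) stop("all abundances are zero")
  p / s
}

#' Neutral Hill number of order q = 1
#'
#' The effective number of equally-abundant taxa: `exp(-sum p_i ln p_i)`,
#' the exponential of Shannon entropy (zero-abundance taxa are skipped).
#' Equals the number of taxa with nonzero abundance iff abundances are
#' uniform.
#'
#' @param p non-negative abundance vector (renormalized to proportions).
#' @return scalar effective number of taxa.
#' @export
hill_neutral_q1 <- function(p) {
  p <- check_props(p)
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

#' Phylogenetic Hill number of order q = 1
#'
#' Mean-effective-lineages form. With branch set `B`, branch abundance
#' `a_b` = summed proportions of the tips descending from the branch, and
#' abundance-weighted tree depth `T = sum_b L_b a_b`, returns
#' `exp(-sum_b (L_b / T) a_b ln a_b)` (the q -> 1 limit). On a star tree
#' with equal branch lengths this reduces to [hill_neutral_q1()].
#'
#' @param p named non-negative abundance vector; names are tree tip labels.
#' @param tree a rooted `phylo` object with branch lengths.
#' @return scalar effective diversity.
#' @export
hill_phylo_q1 <- function(p, tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (is.null(names(p))) stop("abundances must be named by tip label")
  missing <- setdiff(names(p), tree$tip.label)
  if (length(missing))
    stop("taxa missing from the tree: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  p <- check_props(p)
  ab <- branch_abundances(tree, p)
  keep <- ab$a > 0 & ab$len > 0
  len <- ab$len[keep]; a <- ab$a[keep]
  tbar <- sum(len * a)
  if (tbar == 0) stop("tree has zero abundance-weighted depth")
  exp(-sum((len / tbar) * a * log(a)))
}

# Per-edge abundance: sum of the proportions of the tips descending from the
# edge's child node (postorder accumulation).
branch_abundances <- function(tree, p) {
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  node_mass <- numeric(ntip + tree$Nnode)
  node_mass[seq_len(ntip)] <- p[tree$tip.label]
  for (i in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[i, 1L]; child <- tree$edge[i, 2L]
    node_mass[parent] <- node_mass[parent] + node_mass[child]
  }
  list(len = tree$edge.length, a = node_mass[tree$edge[, 2L]])
}

#' Functional Hill number of order q = 1
#'
#' Rao-quadratic-entropy-based form. With `Q = sum_ij d_ij p_i p_j`, returns
#' `exp(-sum_ij (d_ij / Q) p_i p_j ln(p_i p_j))` (the q -> 1 limit of the
#' distance-weighted pair diversity). Invariant to rescaling the distance
#' matrix by a positive constant. Two maximally distinct taxa at equal
#' abundance give 4 (the effective number of equally-distinct pairs is the
#' square of the effective number of taxa).
#'
#' @param p non-negative abundance vector.
#' @param d symmetric pairwise trait-distance matrix with zero diagonal (a
#'   `dist` object is accepted); defaults in the pipeline to Euclidean
#'   distances on the GIFT matrix.
#' @return scalar effective diversity.
#' @export
hill_functional_q1 <- function(p, d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (length(p) != nrow(d)) stop("abundances and distances disagree in size")
  if (anyNA(d) || any(!is.finite(d))) stop("distances must be finite")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  p <- check_props(p)
  pp <- outer(p, p)
  q_rao <- sum(d * pp)
  if (q_rao == 0)
    stop("degenerate input: all abundant taxa are functionally identical (Q = 0)")
  nz <- pp > 0
  exp(-sum((d[nz] / q_rao) * pp[nz] * log(pp[nz])))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared dissimilarities and eigendecomposes; axes are
#' ordered by decreasing eigenvalue, coordinates are eigenvectors scaled by
#' the square roots of their (positive) eigenvalues. Negative eigenvalues —
#' possible for non-Euclidean dissimilarities such as Bray-Curtis — are
#' reported but their axes dropped.
#'
#' @param dist a `dist` object or symmetric zero-diagonal matrix.
#' @param k maximum number of axes to return (capped at the number of
#'   positive eigenvalues).
#' @return object of class `pcoa_result`: list with `points` (n x k'
#'   coordinate matrix), `eig` (all eigenvalues, decreasing) and
#'   `var_explained` (share of the positive eigenvalue sum per kept axis).
#' @export
pcoa <- function(dist, k = 2) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square")
  if (any(abs(d - t(d)) > 1e-8)) stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  if (n < 2L) stop("need at least two objects")
  b <- -0.5 * d^2
  b <- sweep(b, 1L, rowMeans(b))
  b <- sweep(b, 2L, colMeans(b))  # second sweep uses updated column means
  ev <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(ev$values), 1e-300) * 1e-9
  pos <- which(ev$values > tol)
  keep <- utils::head(pos, k)
  if (length(keep)) {
    pts <- ev$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(ev$values[keep]), nrow = length(keep))
    dimnames(pts) <- list(rownames(d), paste0("axis", seq_along(keep)))
  } else {  # all objects coincide: no informative axes
    pts <- matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(rownames(d), NULL))
  }
  structure(list(points = pts, eig = ev$values,
                 var_explained = ev$values[keep] / sum(ev$values[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$points), "objects,", ncol(x$points), "axes kept\n")
  cat("Variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  neg <- sum(x$eig < 0)
  if (neg) cat(neg, "negative eigenvalue(s) dropped\n")
  invisible(x)
}

#' Per-sample alpha-diversity table
#'
#' Computes the three q = 1 Hill numbers (neutral, phylogenetic, functional)
#' for every sample column of a relative-abundance matrix. Samples whose
#' column is all zero (e.g. everything removed by the coverage filter) are
#' excluded with a warning rather than failing the batch.
#'
#' @param rel MAG x sample relative-abundance matrix.
#' @param tree rooted `phylo` covering the MAGs (for the phylogenetic
#'   component; skipped when `NULL`).
#' @param traits genome x trait matrix (for the functional component; skipped
#'   when `NULL`). Pairwise distances are `dist_fun` applied to its rows.
#' @param dist_fun function building the trait distance matrix; defaults to
#'   Euclidean distances.
#' @return data frame with columns `sample`, `neutral`, and where inputs
#'   allow, `phylogenetic` and `functional`.
#' @export
diversity_table <- function(rel, tree = NULL, traits = NULL,
                            dist_fun = function(x) stats::dist(x)) {
  stop_if_not_matrix_like(rel, "relative abundance")
  ok <- !is.na(colSums(rel)) & colSums(rel) > 0
  if (!all(ok))
    warning("excluding empty sample(s): ",
            paste(colnames(rel)[!ok], collapse = ", "))
  rel <- rel[, ok, drop = FALSE]
  out <- data.frame(sample = colnames(rel),
                    neutral = apply(rel, 2L, hill_neutral_q1),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(tree))
    out$phylogenetic <- apply(rel, 2L, function(p)
      hill_phylo_q1(stats::setNames(p, rownames(rel)), tree))
  if (!is.null(traits)) {
    d <- as.matrix(dist_fun(traits[rownames(rel), , drop = FALSE]))
    out$functional <- apply(rel, 2L, function(p) hill_functional_q1(p, d))
  }
  out
}
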