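# Per-taxon temporal / body-weight responses with a bootstrap sign-support
# classification, the MCI-response correlation, the phylogenetic correlogram
# and bootstrap group comparisons.

#' Percentile bootstrap confidence interval for a mean
#'
#' Nonparametric case resampling: `n_boot` resamples of the values with
#' replacement, percentile interval of the resampled means.
#'
#' @param x numeric vector, length >= 2.
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level (default 0.95).
#' @param seed optional integer; when given, results are reproducible
#'   bit-identically and the caller's RNG stream is left untouched.
#' @return named vector `c(mean, lower, upper)`.
#' @export
bootstrap_ci_mean <- function(x, n_boot = 10000, level = 0.95, seed = NULL) {
  stopifnot(is.numeric(x), length(x) >= 2L, !anyNA(x),
            level > 0, level < 1)
  with_seed(seed, {
    n <- length(x)
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    means <- rowMeans(matrix(x[idx], nrow = n_boot, ncol = n))
    alpha <- (1 - level) / 2
    ci <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
    c(mean = mean(x), lower = ci[1], upper = ci[2])
  })
}

#' Temporal or body-weight response of one taxon
#'
#' The per-taxon stand-in for a joint hierarchical species model: ordinary
#' least squares of the transformed abundance (default `log1p`, defined at
#' zero and strictly monotone) on the predictor (age in days, or body weight
#' in g) plus optional covariates as dummy-coded fixed effects. Direction is
#' classified by case-resampling bootstrap sign support: the fraction of
#' bootstrap slopes agreeing with the better-supported sign, compared against
#' a support threshold (default 0.9, the support level used for reporting
#' increasing/decreasing taxa).
#'
#' Support is invariant to affine rescaling of the predictor, and results are
#' reproducible bit-identically for a fixed seed.
#'
#' @param abund numeric vector of one MAG's abundances across samples
#'   (e.g. RPMM).
#' @param predictor numeric vector, same length; must not be constant.
#' @param covariates optional data frame of per-sample covariates
#'   (numeric or categorical).
#' @param n_boot bootstrap resamples (default 500).
#' @param seed integer seed for the bootstrap.
#' @param threshold sign-support threshold for calling a direction.
#' @param transform abundance transform applied before fitting.
#' @param genome_id optional label carried into the result.
#' @return object of class `taxon_response`: list with `genome_id`, `slope`,
#'   `support` (in `[0.5, 1]`), `direction` (`increase`/`decrease`/`none`),
#'   `n`, `n_boot`, `threshold`.
#' @export
taxon_response <- function(abund, predictor, covariates = NULL,
                           n_boot = 500, seed = NULL, threshold = 0.9,
                           transform = log1p, genome_id = NA_character_) {
  n <- length(abund)
  if (length(predictor) != n) stop("abund and predictor lengths differ")
  if (n < 8L) stop("need at least 8 samples")
  if (anyNA(abund) || anyNA(predictor)) stop("NA in abundance or predictor")
  if (stats::sd(predictor) == 0) stop("predictor is constant")
  y <- transform(abund)
  if (is.null(covariates)) {
    x_mat <- cbind(`(Intercept)` = 1, predictor = predictor)
  } else {
    stopifnot(is.data.frame(covariates), nrow(covariates) == n)
    x_mat <- stats::model.matrix(~ predictor + .,
                                 data = cbind(predictor = predictor,
                                              covariates))
  }
  if (n < ncol(x_mat) + 2L)
    stop("fewer samples than model parameters")
  slope <- stats::lm.fit(x_mat, y)$coefficients["predictor"]
  boot_slopes <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x_mat[idx, , drop = FALSE]
      if (qr(xb)$rank < ncol(xb)) return(NA_real_)
      stats::lm.fit(xb, y[idx])$coefficients["predictor"]
    }, numeric(1))
  })
  boot_slopes <- boot_slopes[!is.na(boot_slopes)]
  if (!length(boot_slopes)) stop("all bootstrap fits were degenerate")
  support <- max(mean(boot_slopes > 0) + 0.5 * mean(boot_slopes == 0),
                 mean(boot_slopes < 0) + 0.5 * mean(boot_slopes == 0))
  direction <- if (support >= threshold && slope > 0) "increase"
               else if (support >= threshold && slope < 0) "decrease"
               else "none"
  structure(list(genome_id = genome_id, slope = unname(slope),
                 support = support, direction = direction,
                 n = n, n_boot = n_boot, threshold = threshold),
            class = "taxon_response")
}

#' @export
print.taxon_response <- function(x, ...) {
  cat(sprintf("Taxon response%s: slope %.4g, support %.3f -> %s (n = %d)\n",
              if (is.na(x$genome_id)) "" else paste0(" [", x$genome_id, "]"),
              x$slope, x$support, x$direction, x$n))
  invisible(x)
}

#' Responses of every taxon in an abundance matrix
#'
#' Applies [taxon_response()] row-wise; each taxon gets its own
#' reproducible bootstrap stream derived from `seed`.
#'
#' @param abund MAG x sample abundance matrix (e.g. RPMM).
#' @inheritParams taxon_response
#' @return data frame with columns `genome`, `slope`, `support`, `direction`.
#' @export
taxon_responses <- function(abund, predictor, covariates = NULL,
                            n_boot = 500, seed = NULL, threshold = 0.9,
                            transform = log1p) {
  stop_if_not_matrix_like(abund, "abundance matrix")
  seeds <- if (is.null(seed)) vector("list", nrow(abund))
           else as.list(seed + seq_len(nrow(abund)))
  rows <- lapply(seq_len(nrow(abund)), function(i) {
    r <- taxon_response(abund[i, ], predictor, covariates,
                        n_boot = n_boot, seed = seeds[[i]],
                        threshold = threshold, transform = transform,
                        genome_id = rownames(abund)[i])
    data.frame(genome = r$genome_id, slope = r$slope, support = r$support,
               direction = r$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Community-level summary of response directions
#'
#' @param responses data frame from [taxon_responses()] (or a character
#'   vector of directions).
#' @return named numeric vector of the fractions of taxa classified
#'   `increase`, `decrease` and `none`; sums to 1.
#' @export
classify_community <- function(responses) {
  dirs <- if (is.data.frame(responses)) responses$direction else responses
  if (!length(dirs)) stop("no responses")
  dirs <- factor(dirs, levels = c("increase", "decrease", "none"))
  if (anyNA(dirs)) stop("unknown direction label")
  fr <- as.vector(table(dirs)) / length(dirs)
  stats::setNames(fr, levels(dirs))
}

#' Correlation between per-taxon MCI and response slope
#'
#' Pearson correlation between each taxon's metabolic capacity and its fitted
#' response (e.g. to age), with a permutation p-value: slopes are permuted
#' across taxa and the two-sided exceedance fraction reported with the +1
#' correction.
#'
#' @param mci_values numeric vector of per-taxon MCI.
#' @param slopes numeric vector of per-taxon response slopes, same order.
#' @param n_perm number of label permutations (>= 999 recommended).
#' @param seed integer seed for the permutations.
#' @return list with `r`, `p_value`, `n`, `n_perm`.
#' @export
mci_response_correlation <- function(mci_values, slopes, n_perm = 999,
                                     seed = NULL) {
  if (length(mci_values) != length(slopes)) stop("vectors differ in length")
  if (length(mci_values) < 5L) stop("need at least 5 taxa")
  if (anyNA(mci_values) || anyNA(slopes)) stop("NA in inputs")
  if (stats::sd(mci_values) == 0 || stats::sd(slopes) == 0)
    stop("zero variance in MCI or slopes")
  r_obs <- stats::cor(mci_values, slopes)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      stats::cor(mci_values, sample(slopes)), numeric(1))
  })
  p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_perm + 1)
  list(r = r_obs, p_value = p, n = length(mci_values), n_perm = n_perm)
}

# Moran's I with a binary symmetric weight matrix:
# I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2.
moran_i <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  s0 <- sum(w)
  if (s0 == 0) return(NA_real_)
  (n / s0) * sum(w * outer(z, z)) / sum(z^2)
}

#' Phylogenetic correlogram of per-taxon responses
#'
#' Bins patristic (tree) distances between taxa into equal-frequency classes
#' and computes Moran's I of the response values within each class, with
#' binary weights (pair in class = 1). Positive I at short distances means
#' closely related taxa respond alike. The null expectation of Moran's I is
#' `-1 / (n - 1)`.
#'
#' @param responses named numeric vector of per-taxon values (names are tip
#'   labels).
#' @param tree rooted `phylo` containing all taxa.
#' @param n_classes number of distance classes (must not exceed the number of
#'   taxon pairs).
#' @return data frame with columns `class`, `d_lower`, `d_upper`, `n_pairs`,
#'   `moran_i`, `expected`.
#' @export
phylo_correlogram <- function(responses, tree, n_classes = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(responses))) stop("responses must be named by tip label")
  missing <- setdiff(names(responses), tree$tip.label)
  if (length(missing))
    stop("taxa missing from the tree: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  n <- length(responses)
  n_pairs <- n * (n - 1) / 2
  if (n_classes > n_pairs)
    stop("n_classes exceeds the number of taxon pairs")
  d_full <- ape::cophenetic.phylo(tree)[names(responses), names(responses)]
  dvec <- d_full[upper.tri(d_full)]
  breaks <- unique(stats::quantile(dvec, probs = seq(0, 1, length.out =
                                                       n_classes + 1)))
  if (length(breaks) == 1L)  # all pairwise distances equal: one class
    breaks <- c(breaks - max(abs(breaks) * 1e-9, 1e-12), breaks)
  cls <- matrix(0L, n, n)
  cls[upper.tri(cls)] <- as.integer(cut(dvec, breaks, include.lowest = TRUE))
  cls <- cls + t(cls)
  out <- lapply(seq_len(length(breaks) - 1L), function(k) {
    w <- (cls == k) * 1
    data.frame(class = k, d_lower = breaks[k], d_upper = breaks[k + 1L],
               n_pairs = sum(w) / 2, moran_i = moran_i(responses, w),
               expected = -1 / (n - 1))
  })
  do.call(rbind, out)
}

#' Bootstrap comparison of a trait between taxon groups
#'
#' Percentile bootstrap confidence interval of each group's mean, and a
#' pairwise verdict: two groups are `distinct` when their intervals are
#' disjoint, `overlapping` otherwise (non-overlap of bootstrap intervals as
#' the evidence rule for a group difference).
#'
#' @param values numeric vector of per-taxon trait values.
#' @param groups factor or character vector of group labels, same length;
#'   every group must have at least 2 members.
#' @param n_boot bootstrap resamples per group.
#' @param level confidence level.
#' @param seed integer seed.
#' @return object of class `group_comparison`: list with `groups` (data frame
#'   `group`, `n`, `mean`, `lower`, `upper`) and `verdicts` (data frame
#'   `group1`, `group2`, `verdict`).
#' @export
group_compare_bootstrap <- function(values, groups, n_boot = 10000,
                                    level = 0.95, seed = NULL) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  labs <- sort(unique(groups))
  cis <- lapply(seq_along(labs), function(i)
    bootstrap_ci_mean(values[groups == labs[i]], n_boot = n_boot,
                      level = level,
                      seed = if (is.null(seed)) NULL else seed + i))
  gtab <- data.frame(group = labs, n = as.vector(sizes[labs]),
                     mean = vapply(cis, `[[`, numeric(1), "mean"),
                     lower = vapply(cis, `[[`, numeric(1), "lower"),
                     upper = vapply(cis, `[[`, numeric(1), "upper"),
                     stringsAsFactors = FALSE)
  pairs <- utils::combn(labs, 2L)
  verdicts <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         stringsAsFactors = FALSE)
  verdicts$verdict <- vapply(seq_len(ncol(pairs)), function(j) {
    a <- gtab[gtab$group == pairs[1L, j], ]
    b <- gtab[gtab$group == pairs[2L, j], ]
    if (a$upper < b$lower || b$upper < a$lower) "distinct" else "overlapping"
  }, character(1))
  structure(list(groups = gtab, verdicts = verdicts, level = level),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Bootstrap group comparison (%.0f%% percentile intervals)\n",
              100 * x$level))
  print(x$groups, row.names = FALSE)
  print(x$verdicts, row.names = FALSE)
  invisible(x)
}
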