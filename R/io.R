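# File readers/writers and the end-to-end pipeline runner. TSV with header is
# the canonical dialect (UTF-8, "." decimal, no quoting).

#' Read a labelled numeric matrix from TSV
#'
#' First column holds row labels (its header names the label dimension),
#' remaining columns are numeric.
#'
#' @param path TSV file.
#' @return numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  tab <- read_delim_auto(path)
  if (ncol(tab) < 2L) stop("matrix table needs a label column plus data: ",
                           path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell(s) in matrix table: ", path)
  rownames(m) <- as.character(tab[[1L]])
  if (anyDuplicated(rownames(m))) stop("duplicate row label(s) in ", path)
  m
}

#' Write a labelled numeric matrix as TSV
#'
#' @param m matrix with dimnames.
#' @param path output TSV.
#' @param label header for the row-label column.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(m, path, label = "id") {
  stop_if_not_matrix_like(m, "matrix")
  out <- data.frame(rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[1L] <- label
  write_delim_auto(out, path)
}

#' Read and validate a delimited table against a column schema
#'
#' @param path TSV/CSV file.
#' @param schema named character vector: column name -> one of `"character"`,
#'   `"numeric"`, `"integer"`; integer columns must be non-negative whole
#'   numbers.
#' @param key optional column whose values must be unique.
#' @return validated data frame (typed columns).
#' @export
read_checked_table <- function(path, schema, key = NULL) {
  tab <- read_delim_auto(path)
  missing <- setdiff(names(schema), names(tab))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  for (col in names(schema)) {
    v <- tab[[col]]
    if (schema[[col]] %in% c("numeric", "integer")) {
      v <- suppressWarnings(as.numeric(v))
      if (anyNA(v) && !anyNA(tab[[col]]))
        stop("non-numeric cell in numeric column '", col, "' of ", path)
      if (schema[[col]] == "integer" &&
          any(v[!is.na(v)] < 0 | v[!is.na(v)] %% 1 != 0))
        stop("column '", col, "' of ", path,
             " must hold non-negative integers")
      tab[[col]] <- v
    } else {
      tab[[col]] <- as.character(v)
    }
  }
  if (!is.null(key) && anyDuplicated(tab[[key]]))
    stop("duplicate key value(s) in column '", key, "' of ", path)
  tab
}

#' Read a rooted phylogenetic tree
#'
#' Newick with branch lengths; tip labels must be unique, the tree rooted
#' (no basal trifurcation), and branch lengths present and non-negative.
#'
#' @param path newick file.
#' @return a `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s) in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!ape::is.rooted(tree))
    stop("tree is unrooted (trifurcating root); root it before use")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length(s) in tree")
  tree
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a simulated scenario as a file bundle
#'
#' Materializes every pipeline input as plain text: trait database and
#' category map (CSV), annotations, counts, breadth, genome lengths,
#' per-sample read totals, sample metadata, gene counts (TSV), the tree
#' (newick), and a YAML manifest recording seed and config hash.
#'
#' @param scenario a [simulate_scenario()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "gift_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_trait_db(scenario$genomes$db, p("trait_db.csv"),
                 p("trait_categories.csv"))
  ann <- scenario$genomes$annotations
  write_delim_auto(data.frame(
    genome = rep(names(ann), lengths(ann)),
    gene = paste0(rep(names(ann), lengths(ann)), "@",
                  unlist(ann, use.names = FALSE)),
    identifier = unlist(ann, use.names = FALSE),
    stringsAsFactors = FALSE), p("annotations.tsv"))
  ab <- scenario$abundance
  write_tsv_matrix(ab$counts, p("counts.tsv"), "genome")
  write_tsv_matrix(ab$breadth, p("breadth.tsv"), "genome")
  write_delim_auto(data.frame(genome = names(ab$genome_length_bp),
                              length_bp = unname(ab$genome_length_bp)),
                   p("genome_lengths.tsv"))
  write_delim_auto(data.frame(sample = colnames(ab$counts),
                              total_read_pairs =
                                unname(ab$total_read_pairs),
                              mapped_read_pairs =
                                unname(ab$mapped_read_pairs)),
                   p("read_totals.tsv"))
  write_delim_auto(scenario$metadata, p("sample_metadata.tsv"))
  tt <- scenario$transcripts
  write_delim_auto(cbind(tt$genes, as.data.frame(tt$counts)),
                   p("gene_counts.tsv"))
  ape::write.tree(scenario$tree, p("tree.nwk"))
  yaml::write_yaml(list(seed = scenario$seed,
                        config_hash = config_hash(scenario$config),
                        config = unclass(scenario$config)),
                   p("manifest.yml"))
  invisible(dir)
}

#' Read a scenario bundle back from files
#'
#' Inverse of [write_scenario()] for the analysis-facing inputs (the
#' generator truth is not part of the file contract).
#'
#' @param dir directory written by [write_scenario()] (or assembled by hand
#'   to the same layout).
#' @return list with `db`, `annotations`, `abundance`, `metadata`,
#'   `transcripts`, `tree`, `manifest`.
#' @export
read_scenario <- function(dir) {
  p <- function(f) file.path(dir, f)
  db <- parse_trait_db(p("trait_db.csv"),
                       if (file.exists(p("trait_categories.csv")))
                         p("trait_categories.csv") else NULL)
  ann_tab <- read_checked_table(p("annotations.tsv"),
                                c(genome = "character", gene = "character",
                                  identifier = "character"))
  counts <- read_tsv_matrix(p("counts.tsv"))
  breadth <- read_tsv_matrix(p("breadth.tsv"))
  lens <- read_checked_table(p("genome_lengths.tsv"),
                             c(genome = "character", length_bp = "numeric"),
                             key = "genome")
  totals <- read_checked_table(p("read_totals.tsv"),
                               c(sample = "character",
                                 total_read_pairs = "integer",
                                 mapped_read_pairs = "integer"),
                               key = "sample")
  metadata <- read_checked_table(
    p("sample_metadata.tsv"),
    c(sample = "character", day = "numeric", trial = "character",
      pen = "character", sex = "character", line = "character",
      treatment = "character", body_weight_g = "numeric"),
    key = "sample")
  gc_tab <- read_delim_auto(p("gene_counts.tsv"))
  gene_cols <- c("gene", "genome", "identifier", "length_bp")
  tcounts <- as.matrix(gc_tab[, setdiff(names(gc_tab), gene_cols),
                              drop = FALSE])
  rownames(tcounts) <- gc_tab$gene
  transcripts <- transcript_table(gc_tab[, gene_cols], tcounts)
  abundance <- abundance_table(
    counts, breadth,
    stats::setNames(lens$length_bp, lens$genome),
    stats::setNames(totals$total_read_pairs, totals$sample),
    stats::setNames(totals$mapped_read_pairs, totals$sample))
  manifest <- if (file.exists(p("manifest.yml")))
    yaml::read_yaml(p("manifest.yml")) else NULL
  list(db = db, annotations = annotation_sets(ann_tab),
       abundance = abundance, metadata = metadata,
       transcripts = transcripts, tree = read_tree(p("tree.nwk")),
       manifest = manifest)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on an input bundle
#'
#' Executes distillation, abundance normalization, diversity, community
#' profiling, per-taxon dynamics and expression profiling, writing every
#' result table as TSV plus a JSON run manifest (package version, seed,
#' config hash). Re-running on the same inputs with the same seed produces
#' byte-identical outputs.
#'
#' @param input a directory in the [write_scenario()] layout, a
#'   `gift_scenario`, or a list as returned by [read_scenario()].
#' @param out_dir output directory (created if needed).
#' @param coverage_threshold breadth threshold for [filter_by_coverage()].
#' @param support_threshold sign-support threshold for direction calls.
#' @param mci_low,mci_high capacity-class boundaries.
#' @param ci_level bootstrap confidence level for group comparisons.
#' @param n_boot bootstrap resamples for per-taxon responses.
#' @param n_boot_groups bootstrap resamples for group comparisons.
#' @param seed integer seed for all stochastic stages.
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(input, out_dir,
                         coverage_threshold = 0.30,
                         support_threshold = 0.90,
                         mci_low = 0.15, mci_high = 0.30,
                         ci_level = 0.95,
                         n_boot = 500, n_boot_groups = 2000,
                         seed = 1L) {
  stopifnot(coverage_threshold > 0, coverage_threshold <= 1,
            support_threshold > 0.5, support_threshold <= 1,
            mci_low < mci_high, ci_level > 0, ci_level < 1)
  seed <- as.integer(seed)
  if (is.character(input)) input <- run_stage("read", read_scenario(input))
  if (inherits(input, "gift_scenario"))
    input <- list(db = input$genomes$db,
                  annotations = input$genomes$annotations,
                  abundance = input$abundance, metadata = input$metadata,
                  transcripts = input$transcripts, tree = input$tree)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  md <- input$metadata[match(colnames(input$abundance$counts),
                             input$metadata$sample), , drop = FALSE]

  gifts <- run_stage("distill", distill_catalogue(input$annotations,
                                                  input$db))
  mci_tab <- mci_table(gifts, mci_low, mci_high)
  write_tsv_matrix(gifts, p("gift_matrix.tsv"), "genome")
  write_delim_auto(mci_tab, p("mci.tsv"))

  filt <- run_stage("abundance",
                    filter_by_coverage(input$abundance, coverage_threshold))
  rp <- rpmm(filt)
  rel <- suppressWarnings(relative_abundance(filt))
  write_tsv_matrix(rp, p("rpmm.tsv"), "genome")
  write_tsv_matrix(rel, p("relative_abundance.tsv"), "genome")
  write_delim_auto(data.frame(sample = colnames(filt$counts),
                              percent_mapped =
                                unname(percent_mapped(filt))),
                   p("percent_mapped.tsv"))

  div <- run_stage("diversity",
                   suppressWarnings(diversity_table(rel, input$tree, gifts)))
  write_delim_auto(div, p("diversity.tsv"))

  prof <- run_stage("community", {
    ok <- !is.na(colSums(rel))
    suppressWarnings(community_weighted_gifts(rel[, ok, drop = FALSE],
                                              gifts))
  })
  write_tsv_matrix(prof$cw_gifts, p("community_gifts.tsv"), "sample")
  write_delim_auto(data.frame(sample = rownames(prof$cw_gifts),
                              community_mci =
                                unname(prof$community_mci)),
                   p("community_mci.tsv"))

  dyn <- run_stage("dynamics", {
    covars <- md[, c("trial", "sex", "line", "treatment"), drop = FALSE]
    temporal <- taxon_responses(rp, md$day, covars, n_boot = n_boot,
                                seed = seed, threshold = support_threshold)
    fractions <- classify_community(temporal)
    mci_v <- stats::setNames(mci_tab$mci, mci_tab$genome)[temporal$genome]
    corr <- mci_response_correlation(mci_v, temporal$slope,
                                     n_perm = 999, seed = seed + 1L)
    correlogram <- phylo_correlogram(
      stats::setNames(temporal$slope, temporal$genome), input$tree)
    d35 <- md$day == max(md$day) & !is.na(md$body_weight_g)
    weightresp <- taxon_responses(
      rp[, d35, drop = FALSE], md$body_weight_g[d35],
      md[d35, c("trial", "sex", "line", "treatment"), drop = FALSE],
      n_boot = n_boot, seed = seed + 2L, threshold = support_threshold)
    assoc <- c(increase = "positive", decrease = "negative",
               none = "none")[weightresp$direction]
    tab_assoc <- table(assoc)
    cmp_keep <- assoc %in% names(tab_assoc)[tab_assoc >= 2]
    comp <- if (length(unique(assoc[cmp_keep])) >= 2)
      group_compare_bootstrap(
        stats::setNames(mci_tab$mci,
                        mci_tab$genome)[weightresp$genome[cmp_keep]],
        assoc[cmp_keep], n_boot = n_boot_groups, level = ci_level,
        seed = seed + 3L)
    else NULL
    list(temporal = temporal, fractions = fractions, corr = corr,
         correlogram = correlogram, weight = weightresp,
         weight_assoc = assoc, comparison = comp)
  })
  write_delim_auto(dyn$temporal, p("temporal_responses.tsv"))
  write_delim_auto(cbind(dyn$weight,
                         association = unname(dyn$weight_assoc)),
                   p("weight_responses.tsv"))
  write_delim_auto(dyn$correlogram, p("phylo_correlogram.tsv"))
  write_delim_auto(data.frame(
    statistic = c("fraction_increase", "fraction_decrease", "fraction_none",
                  "mci_slope_r", "mci_slope_p"),
    value = c(unname(dyn$fractions), dyn$corr$r, dyn$corr$p_value)),
    p("dynamics_summary.tsv"))
  if (!is.null(dyn$comparison)) {
    write_delim_auto(dyn$comparison$groups, p("group_means.tsv"))
    write_delim_auto(dyn$comparison$verdicts, p("group_verdicts.tsv"))
  }

  expr <- run_stage("expression", {
    em <- expression_by_gift(input$transcripts, input$db,
                             pooling = "pooled", normalized = TRUE)
    reduced <- detect_genome_reduced(input$transcripts, input$db,
                                     genomes = rownames(gifts))
    ord <- suppressWarnings(expression_ordination(em))
    list(expression = em, reduced = reduced, ordination = ord)
  })
  write_tsv_matrix(expr$expression, p("gift_expression.tsv"), "genome")
  write_delim_auto(expr$reduced, p("genome_reduced.tsv"))
  write_tsv_matrix(expr$ordination$points, p("expression_pcoa.tsv"),
                   "genome")

  manifest <- list(package = "magifts",
                   version = as.character(utils::packageVersion("magifts")),
                   seed = seed,
                   parameters = list(coverage_threshold = coverage_threshold,
                                     support_threshold = support_threshold,
                                     mci_low = mci_low, mci_high = mci_high,
                                     ci_level = ci_level, n_boot = n_boot,
                                     n_boot_groups = n_boot_groups),
                   config_hash = config_hash(
                     list(coverage_threshold, support_threshold, mci_low,
                          mci_high, ci_level, n_boot, n_boot_groups, seed)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             p("run_manifest.json"))
  invisible(list(gifts = gifts, mci = mci_tab, filtered = filt, rpmm = rp,
                 relative_abundance = rel, diversity = div, profile = prof,
                 dynamics = dyn, expression = expr))
}
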