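# Synthetic-data generator. Emulates the seven pipeline inputs with a planted
# generalist-to-specialist succession: a genome catalogue whose metabolic
# capacity evolves on a phylogeny, temporal abundance trends anticorrelated
# with capacity, body weights driven by a few strong positive and many
# diffuse negative taxon effects, and transcript tables with two planted
# genome-reduced expression guilds.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults describe the emulated study conditions: three cross-sectional
#' sampling days (7, 21, 35), two trials, a negative correlation between a
#' taxon's metabolic capacity and its temporal trend, a positive/negative
#' body-weight association split in a 10:190 proportion of the catalogue
#' (a handful of strong positive associates among many diffuse negatives), and per-sample sequencing effort with ~67% of reads mapping to
#' the catalogue. All parameters are exposed; see the methods vignette for
#' the rationale behind each default.
#'
#' @param n_taxa number of MAGs.
#' @param n_samples_per_day animals sampled (cross-sectionally) per day.
#' @param days sampling days.
#' @param n_gifts number of GIFT elements in the generated trait database
#'   (>= 16; the anchor elements are always included).
#' @param generalist_fraction fraction of taxa labelled generalist (top MCI).
#' @param mci_slope_correlation target correlation between taxon MCI and
#'   temporal slope, in (-1, 1).
#' @param n_positive_assoc,n_negative_assoc planted body-weight-associated
#'   taxa; defaults scale a 10:190 split of an 822-genome catalogue to
#'   `n_taxa`.
#' @param slope_mean,slope_sd mean and sd of per-day log-abundance slopes.
#' @param intercept_sd sd of per-taxon baseline log abundances.
#' @param intercept_mci_correlation correlation between a taxon's baseline
#'   log abundance and its MCI. Positive by default: metabolically versatile
#'   generalists dominate the early community, the defining feature of the
#'   emulated succession (their later decline is what lets the rest of the
#'   community rise in relative terms).
#' @param slope_intercept_reversion in `[0, 1)`: how strongly the
#'   non-capacity component of a taxon's slope reverts its non-capacity
#'   baseline advantage. High values contract the log-abundance spread over
#'   the trial, so community evenness (and with it every diversity metric)
#'   rises with age while the configured MCI-slope correlation is preserved
#'   exactly.
#' @param sample_noise_sd sd of per-sample log-abundance noise.
#' @param depth_mean,depth_sdlog lognormal read-pair depth per sample.
#' @param read_pair_bp bases contributed by one read pair (2 x 150 bp).
#' @param breadth_noise_sd logit-scale noise on breadth of coverage.
#' @param mapped_fraction_mean,mapped_fraction_sd per-sample fraction of
#'   total reads mapping to the catalogue.
#' @param base_retention median gene-retention probability.
#' @param retention_bm_sd Brownian-motion rate of the logit retention
#'   gradient on the tree.
#' @param genome_base_bp,bp_per_gene,genome_length_noise_sd genome length
#'   model: base + bp per retained pathway gene + Gaussian noise.
#' @param weight_baseline named vector of mean body weight (g) per day.
#' @param weight_noise_sd body-weight noise sd (g) at the final day; earlier
#'   days are scaled by their baseline.
#' @param pos_effect,neg_effect per-taxon body-weight effects of planted
#'   positive/negative taxa, in units of `weight_noise_sd` per sd of relative
#'   abundance. Few strong positives and many diffuse negatives mirror the
#'   association structure characteristic of this system.
#' @param diversity_effect optional direct negative dependence of body
#'   weight on neutral diversity (same units); 0 by default.
#' @param n_rna_samples metatranscriptomic samples (drawn at the final day).
#' @param rna_mu mean negative-binomial transcript count per active gene and
#'   sample.
#' @param nb_size negative-binomial dispersion (size) of transcript counts.
#' @param n_reduced_a,n_reduced_b sizes of the two planted genome-reduced
#'   expression guilds (broad-set and narrow-set).
#' @param gene_length_mean,gene_length_sd gene length distribution (bp).
#' @param seed default seed carried by the config.
#' @return object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(n_taxa = 150,
                            n_samples_per_day = 40,
                            days = c(7, 21, 35),
                            n_gifts = 40,
                            generalist_fraction = 0.35,
                            mci_slope_correlation = -0.6,
                            n_positive_assoc = max(1L, round(10 * n_taxa / 822)),
                            n_negative_assoc = max(2L, round(190 * n_taxa / 822)),
                            slope_mean = 0.03,
                            slope_sd = 0.08,
                            intercept_sd = 2.2,
                            intercept_mci_correlation = 0.8,
                            slope_intercept_reversion = 0.9,
                            sample_noise_sd = 0.6,
                            depth_mean = 2e6,
                            depth_sdlog = 0.3,
                            read_pair_bp = 300,
                            breadth_noise_sd = 0.3,
                            mapped_fraction_mean = 0.67,
                            mapped_fraction_sd = 0.06,
                            base_retention = 0.40,
                            retention_bm_sd = 1.5,
                            genome_base_bp = 1.2e6,
                            bp_per_gene = 9000,
                            genome_length_noise_sd = 1e5,
                            weight_baseline = c("7" = 180, "21" = 950,
                                                "35" = 2200),
                            weight_noise_sd = 150,
                            pos_effect = 2,
                            neg_effect = 0.4,
                            diversity_effect = 0,
                            n_rna_samples = 10,
                            rna_mu = 5,
                            nb_size = 2,
                            n_reduced_a = 6,
                            n_reduced_b = 6,
                            gene_length_mean = 900,
                            gene_length_sd = 200,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_taxa >= 2, cfg$n_samples_per_day >= 1,
            length(cfg$days) >= 1, cfg$n_gifts >= 16,
            cfg$mci_slope_correlation > -1, cfg$mci_slope_correlation < 1,
            cfg$n_positive_assoc + cfg$n_negative_assoc <= cfg$n_taxa,
            cfg$n_reduced_a + cfg$n_reduced_b <= cfg$n_taxa,
            all(as.character(cfg$days) %in% names(cfg$weight_baseline)))
  structure(cfg, class = "scenario_config")
}

# Anchor elements every generated database contains; codes and names follow
# the field's hierarchical convention (domain / function / element).
anchor_gift_specs <- function() {
  list(
    list("B0101", "purine biosynthesis", "Nucleic acid biosynthesis"),
    list("B0102", "pyrimidine biosynthesis", "Nucleic acid biosynthesis"),
    list("B0103", "nucleotide interconversion", "Nucleic acid biosynthesis"),
    list("B0211", "lysine biosynthesis", "Amino acid biosynthesis"),
    list("B0212", "methionine biosynthesis", "Amino acid biosynthesis"),
    list("B0401", "acetate biosynthesis", "SCFA biosynthesis"),
    list("B0402", "butyrate biosynthesis", "SCFA biosynthesis"),
    list("B0403", "propionate biosynthesis", "SCFA biosynthesis"),
    list("B0701", "thiamine biosynthesis", "Vitamin biosynthesis"),
    list("B0702", "riboflavin biosynthesis", "Vitamin biosynthesis"),
    list("B0801", "chorismate biosynthesis", "Aromatic compound biosynthesis"),
    list("B0805", "indole-3-acetate biosynthesis",
         "Aromatic compound biosynthesis"),
    list("D0101", "starch degradation", "Polysaccharide degradation"),
    list("D0102", "cellulose degradation", "Polysaccharide degradation"),
    list("D0509", "arginine degradation", "Amino acid degradation"),
    list("D0510", "lysine degradation", "Amino acid degradation"))
}

#' Generate a synthetic trait database
#'
#' Deterministic (no randomness): the 16 anchor elements used by the planted
#' scenario structure (nucleic-acid biosynthesis B0101-B0103, lysine B0211,
#' SCFA B0401-B0403, thiamine B0701, indole-3-acetate B0805, arginine
#' degradation D0509, ...) plus filler elements up to `n_gifts`, each with
#' 2-4 steps mixing single-identifier clauses, two-identifier joint clauses
#' and alternative clauses. Identifiers are synthetic K-numbers, unique per
#' element.
#'
#' @param n_gifts total number of elements (>= 16).
#' @return a [trait_db()] with a functional category map.
#' @export
simulate_trait_db <- function(n_gifts = 40) {
  stopifnot(n_gifts >= 16)
  anchors <- anchor_gift_specs()
  filler_funs <- list(c("B03", "carbohydrate derivative biosynthesis",
                        "Carbohydrate biosynthesis"),
                      c("B05", "lipid biosynthesis", "Lipid biosynthesis"),
                      c("D02", "sugar degradation", "Sugar degradation"),
                      c("D07", "xenobiotic degradation",
                        "Xenobiotic degradation"))
  specs <- anchors
  i <- 0L
  while (length(specs) < n_gifts) {
    fn <- filler_funs[[i %% length(filler_funs) + 1L]]
    el <- i %/% length(filler_funs) + 1L
    specs[[length(specs) + 1L]] <-
      list(sprintf("%s%02d", fn[1], el),
           sprintf("%s (module %d)", fn[2], el), fn[3])
    i <- i + 1L
  }
  next_id <- 10001L
  elements <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    n_steps <- 2L + (k %% 3L)
    steps <- vector("list", n_steps)
    for (s in seq_len(n_steps)) {
      shape <- (k + s) %% 3L
      if (shape == 0L) {            # one two-identifier joint clause
        steps[[s]] <- list(sprintf("K%05d", next_id + 0:1))
        next_id <- next_id + 2L
      } else if (shape == 1L) {     # two alternative single identifiers
        steps[[s]] <- list(sprintf("K%05d", next_id),
                           sprintf("K%05d", next_id + 1L))
        next_id <- next_id + 2L
      } else {                      # one single-identifier clause
        steps[[s]] <- list(sprintf("K%05d", next_id))
        next_id <- next_id + 1L
      }
    }
    elements[[k]] <- gift_definition(specs[[k]][[1]], specs[[k]][[2]], steps)
  }
  cats <- stats::setNames(vapply(specs, function(x) x[[3]], character(1)),
                          vapply(specs, function(x) x[[1]], character(1)))
  trait_db(elements, cats)
}

#' Simulate a rooted phylogeny of MAGs
#'
#' Pure-birth (Yule) tree with unit speciation rate; tips are relabelled
#' `mag_001 ...`. Deterministic under `seed`.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @return a rooted `phylo` object with branch lengths.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2) stop("need at least 2 taxa")
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  tree$tip.label <- pad_ids("mag", n_taxa)
  tree
}

#' Simulate an annotated genome catalogue on a tree
#'
#' A gene-retention probability per taxon evolves as Brownian motion on the
#' logit scale along the tree (the generalist-specialist gradient); each
#' genome keeps each pathway identifier of the trait database independently
#' with that probability, and genome length grows linearly with the number of
#' retained genes. Two genome-reduced guilds are planted for the expression
#' analyses: both lack every nucleic-acid biosynthesis (B0101-B0103)
#' identifier; guild A additionally carries complete SCFA, thiamine, lysine,
#' indole-3-acetate and arginine-degradation pathways, guild B only the SCFA
#' and thiamine ones. All non-reduced genomes are guaranteed at least one
#' identifier of each of B0101-B0103, so their transcription can be observed.
#'
#' @param tree rooted `phylo` from [simulate_tree()].
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return object of class `mag_genomes`: list with `db`, `annotations`
#'   (named list genome -> identifiers), `genome_length_bp`, `gifts` (GIFT
#'   matrix), `mci` (named vector), `retention`, `reduced_a`, `reduced_b`,
#'   `generalist` (logical), `tree`.
#' @export
simulate_genomes <- function(tree, config = scenario_config(), seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  db <- simulate_trait_db(config$n_gifts)
  id_sets <- db_identifier_sets(db)
  all_ids <- unique(unlist(id_sets, use.names = FALSE))
  nacid <- unlist(id_sets[c("B0101", "B0102", "B0103")], use.names = FALSE)
  guild_a_codes <- c(grep("^B04", gift_codes(db), value = TRUE),
                     "B0701", "B0211", "B0805", "D0509")
  guild_b_codes <- c(grep("^B04", gift_codes(db), value = TRUE), "B0701")
  first_nacid <- vapply(id_sets[c("B0101", "B0102", "B0103")],
                        `[`, character(1), 1L)
  out <- with_seed(seed, {
    bm <- ape::rTraitCont(tree, model = "BM", sigma = config$retention_bm_sd)
    retention <- stats::plogis(stats::qlogis(config$base_retention) +
                                 as.numeric(bm))
    names(retention) <- tree$tip.label
    ord <- order(retention)
    reduced_a <- tree$tip.label[ord[seq_len(config$n_reduced_a)]]
    reduced_b <- tree$tip.label[ord[config$n_reduced_a +
                                      seq_len(config$n_reduced_b)]]
    reduced <- c(reduced_a, reduced_b)
    annotations <- lapply(tree$tip.label, function(g) {
      keep <- all_ids[stats::runif(length(all_ids)) < retention[g]]
      if (g %in% reduced) {
        keep <- setdiff(keep, nacid)
        forced <- if (g %in% reduced_a) guild_a_codes else guild_b_codes
        keep <- union(keep, unlist(id_sets[forced], use.names = FALSE))
      } else {
        keep <- union(keep, first_nacid)
      }
      sort(keep)
    })
    names(annotations) <- tree$tip.label
    len <- config$genome_base_bp +
      config$bp_per_gene * lengths(annotations) +
      stats::rnorm(length(annotations), 0, config$genome_length_noise_sd)
    len <- pmax(round(len), 4e5)
    list(annotations = annotations, retention = retention,
         genome_length_bp = stats::setNames(len, tree$tip.label),
         reduced_a = reduced_a, reduced_b = reduced_b)
  })
  gifts <- distill_catalogue(out$annotations, db)
  mci_vals <- apply(gifts, 1L, mci)
  structure(
    c(out,
      list(db = db, gifts = gifts, mci = mci_vals,
           generalist = mci_vals >= stats::quantile(
             mci_vals, 1 - config$generalist_fraction),
           tree = tree)),
    class = "mag_genomes")
}

#' @export
print.mag_genomes <- function(x, ...) {
  cat("Simulated genome catalogue:", length(x$annotations), "MAGs,",
      ncol(x$gifts), "GIFT elements\n")
  cat(sprintf("MCI range %.3f-%.3f; %d + %d planted genome-reduced taxa\n",
              min(x$mci), max(x$mci),
              length(x$reduced_a), length(x$reduced_b)))
  invisible(x)
}

#' Simulate read-mapping counts and sample metadata
#'
#' Per-taxon temporal slopes of log abundance are drawn so that their
#' correlation with MCI matches the configured target (negative by default:
#' high-capacity generalists decline, low-capacity specialists rise).
#' Expected log abundance is `intercept + slope * day`; per-sample counts are
#' multinomial at a lognormal depth, breadth of coverage is a saturating
#' function of read density with logit-scale noise, and per-sample totals are
#' back-calculated from a ~67% mapped fraction.
#'
#' @param genomes a [simulate_genomes()] result.
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return list with `abundance` (an [abundance_table()]), `metadata`
#'   (data frame: sample, animal, day, trial, pen, sex, line, treatment,
#'   body_weight_g — weights filled by [simulate_weights()]), and `truth`
#'   (intercepts, slopes).
#' @export
simulate_counts <- function(genomes, config = scenario_config(), seed = 1L) {
  stopifnot(inherits(genomes, "mag_genomes"))
  taxa <- names(genomes$annotations)
  n <- length(taxa)
  n_per <- config$n_samples_per_day
  days <- rep(config$days, each = n_per)
  n_samp <- length(days)
  samples <- pad_ids("s", n_samp)
  with_seed(seed, {
    z_mci <- as.numeric(scale(genomes$mci))
    rho <- config$mci_slope_correlation
    rho_i <- config$intercept_mci_correlation
    rho_rev <- config$slope_intercept_reversion
    z_int <- stats::rnorm(n)
    z_eps <- stats::rnorm(n)
    intercepts <- config$intercept_sd *
      (rho_i * z_mci + sqrt(1 - rho_i^2) * z_int)
    # slope residual reverts the non-capacity baseline advantage, so the
    # early dominants decline and evenness rises; corr(slope, MCI) = rho by
    # construction since z_int and z_eps are independent of z_mci
    slopes <- config$slope_mean + config$slope_sd *
      (rho * z_mci - sqrt(1 - rho^2) *
         (rho_rev * z_int + sqrt(1 - rho_rev^2) * z_eps))
    counts <- matrix(0, n, n_samp, dimnames = list(taxa, samples))
    for (s in seq_len(n_samp)) {
      eta <- intercepts + slopes * days[s] +
        stats::rnorm(n, 0, config$sample_noise_sd)
      p <- exp(eta - max(eta))
      depth <- round(stats::rlnorm(1, log(config$depth_mean),
                                   config$depth_sdlog))
      counts[, s] <- stats::rmultinom(1, depth, p / sum(p))
    }
    cov_density <- sweep(counts * config$read_pair_bp, 1L,
                         genomes$genome_length_bp, "/")
    b_true <- pmin(pmax(1 - exp(-cov_density), 1e-9), 1 - 1e-9)
    breadth <- stats::plogis(stats::qlogis(b_true) +
                               stats::rnorm(length(b_true), 0,
                                            config$breadth_noise_sd))
    breadth[counts == 0] <- 0
    mapped <- colSums(counts)
    frac <- pmin(pmax(stats::rnorm(n_samp, config$mapped_fraction_mean,
                                   config$mapped_fraction_sd), 0.30), 0.95)
    total <- round(mapped / frac)
    metadata <- data.frame(
      sample = samples, animal = samples, day = days,
      trial = rep_len(c("A", "B"), n_samp),
      pen = paste0("pen", 1 + (seq_len(n_samp) - 1L) %% 24L),
      sex = rep_len(c("F", "M", "M", "F"), n_samp),
      line = rep_len(c("lineX", "lineX", "lineY", "lineY"), n_samp),
      treatment = rep_len(paste0("T", 1:3), n_samp),
      body_weight_g = NA_real_, stringsAsFactors = FALSE)
    list(abundance = abundance_table(
           counts, breadth, genomes$genome_length_bp,
           stats::setNames(total, samples),
           stats::setNames(mapped, samples)),
         metadata = metadata,
         truth = list(intercepts = stats::setNames(intercepts, taxa),
                      slopes = stats::setNames(slopes, taxa)))
  })
}

#' Simulate body weights with planted taxon associations
#'
#' Weight of each animal is its day's baseline plus planted taxon effects on
#' the standardized relative abundances — a few strong positive taxa (drawn
#' from the broad genome-reduced guild where possible) and many diffuse
#' negative taxa (the highest-capacity eligible taxa, plus the narrow
#' genome-reduced guild) — minus an optional diversity term, plus Gaussian
#' noise. Effect and noise scales are proportional to the day's baseline so
#' early-life weights stay positive.
#'
#' @param counts_sim result of [simulate_counts()].
#' @param genomes the matching [simulate_genomes()] result.
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return `counts_sim` with `metadata$body_weight_g` filled and
#'   `truth$positive_taxa` / `truth$negative_taxa` added.
#' @export
simulate_weights <- function(counts_sim, genomes,
                             config = scenario_config(), seed = 1L) {
  md <- counts_sim$metadata
  final_day <- max(config$days)
  if (!any(md$day == final_day)) stop("no final-day samples")
  rel <- suppressWarnings(relative_abundance(counts_sim$abundance))
  with_seed(seed, {
    day35 <- md$sample[md$day == final_day]
    mean_ab <- rowMeans(rel[, day35, drop = FALSE])
    # associations are planted only among taxa detectable at the final day
    # (breadth above the coverage filter in most samples), mirroring the
    # fact that reported associated taxa are by construction observable
    detect <- rowMeans(counts_sim$abundance$breadth[, day35,
                                                    drop = FALSE] >= 0.30)
    eligible <- names(mean_ab)[detect >= 0.8]
    eligible <- eligible[order(mean_ab[eligible], decreasing = TRUE)]
    need <- config$n_positive_assoc + config$n_negative_assoc
    if (length(eligible) < need)
      eligible <- utils::head(
        c(eligible, setdiff(names(sort(mean_ab, decreasing = TRUE)),
                            eligible)), need)
    pos_pool <- intersect(genomes$reduced_a, eligible)
    if (length(pos_pool) < config$n_positive_assoc)
      pos_pool <- union(pos_pool,
                        eligible[order(genomes$mci[eligible])])
    positive <- pos_pool[seq_len(config$n_positive_assoc)]
    neg_pool <- setdiff(eligible, positive)
    neg_first <- intersect(genomes$reduced_b, neg_pool)
    neg_rest <- setdiff(neg_pool, neg_first)
    neg_rest <- neg_rest[order(genomes$mci[neg_rest], decreasing = TRUE)]
    negative <- utils::head(c(neg_first, neg_rest), config$n_negative_assoc)
    weights <- rep(NA_real_, nrow(md))
    for (d in config$days) {
      idx <- which(md$day == d)
      scale_d <- config$weight_baseline[[as.character(d)]] /
        max(config$weight_baseline)
      zmat <- apply(rel[c(positive, negative), md$sample[idx],
                        drop = FALSE], 1L, function(v) {
        s <- stats::sd(v)
        if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
      })  # samples x taxa
      effs <- c(rep(config$pos_effect, length(positive)),
                rep(-config$neg_effect, length(negative)))
      contrib <- as.numeric(zmat %*% effs)
      if (config$diversity_effect != 0) {
        hills <- apply(rel[, md$sample[idx], drop = FALSE], 2L,
                       hill_neutral_q1)
        zh <- as.numeric(scale(hills))
        contrib <- contrib - config$diversity_effect * zh
      }
      weights[idx] <- config$weight_baseline[[as.character(d)]] +
        scale_d * config$weight_noise_sd *
          (contrib + stats::rnorm(length(idx)))
    }
    counts_sim$metadata$body_weight_g <- round(weights, 1)
    counts_sim$truth$positive_taxa <- positive
    counts_sim$truth$negative_taxa <- negative
    counts_sim
  })
}

#' Simulate a gene-level transcript table
#'
#' Every genome contributes one gene per retained pathway identifier. Active
#' genes receive negative-binomial counts (lognormal per-gene activity,
#' lognormal per-sample depth factor); inactive genes are present with zero
#' counts. The two planted genome-reduced guilds transcribe only their guild
#' gene sets (guild A: SCFA, thiamine, lysine, indole-3-acetate, arginine
#' degradation; guild B: SCFA and thiamine) and carry no nucleic-acid
#' biosynthesis genes at all; every other genome transcribes its full
#' repertoire, including the planted B0101-B0103 genes.
#'
#' @param genomes a [simulate_genomes()] result.
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return a [transcript_table()].
#' @export
simulate_transcripts <- function(genomes, config = scenario_config(),
                                 seed = 1L) {
  stopifnot(inherits(genomes, "mag_genomes"))
  db <- genomes$db
  id_sets <- db_identifier_sets(db)
  guild_a_ids <- unique(unlist(
    id_sets[c(grep("^B04", gift_codes(db), value = TRUE),
              "B0701", "B0211", "B0805", "D0509")], use.names = FALSE))
  guild_b_ids <- unique(unlist(
    id_sets[c(grep("^B04", gift_codes(db), value = TRUE), "B0701")],
    use.names = FALSE))
  taxa <- names(genomes$annotations)
  genes <- do.call(rbind, lapply(taxa, function(g) {
    ids <- genomes$annotations[[g]]
    if (!length(ids)) return(NULL)
    active <- if (g %in% genomes$reduced_a) ids %in% guild_a_ids
              else if (g %in% genomes$reduced_b) ids %in% guild_b_ids
              else rep(TRUE, length(ids))
    data.frame(gene = paste0(g, "@", ids), genome = g, identifier = ids,
               active = active, stringsAsFactors = FALSE)
  }))
  samples <- pad_ids("rs", config$n_rna_samples)
  with_seed(seed, {
    genes$length_bp <- pmax(round(stats::rnorm(nrow(genes),
                                               config$gene_length_mean,
                                               config$gene_length_sd)), 200)
    activity <- stats::rlnorm(nrow(genes), log(config$rna_mu), 0.5)
    depth_factor <- stats::rlnorm(length(samples), 0, 0.3)
    counts <- matrix(0, nrow(genes), length(samples),
                     dimnames = list(genes$gene, samples))
    act <- which(genes$active)
    for (s in seq_along(samples)) {
      counts[act, s] <- stats::rnbinom(length(act), size = config$nb_size,
                                       mu = activity[act] * depth_factor[s])
    }
    transcript_table(genes[, c("gene", "genome", "identifier", "length_bp")],
                     counts)
  })
}

#' Simulate a complete input bundle
#'
#' Runs the whole generator chain — tree, annotated genomes, read-mapping
#' counts and metadata, body weights, transcripts — with sub-seeds derived
#' from `seed`, so the bundle is deterministic under `(config, seed)`.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed; defaults to the config's.
#' @return object of class `gift_scenario`: list with `config`, `tree`,
#'   `genomes`, `abundance`, `metadata`, `transcripts`, `truth`.
#' @seealso [write_scenario()] to materialize the bundle as files,
#'   [run_pipeline()] to analyse it.
#' @export
simulate_scenario <- function(config = scenario_config(),
                              seed = config$seed) {
  seed <- as.integer(seed)
  tree <- simulate_tree(config$n_taxa, seed = seed)
  genomes <- simulate_genomes(tree, config, seed = seed + 1L)
  cs <- simulate_counts(genomes, config, seed = seed + 2L)
  cs <- simulate_weights(cs, genomes, config, seed = seed + 3L)
  transcripts <- simulate_transcripts(genomes, config, seed = seed + 4L)
  structure(list(config = config, seed = seed, tree = tree,
                 genomes = genomes, abundance = cs$abundance,
                 metadata = cs$metadata, transcripts = transcripts,
                 truth = c(cs$truth,
                           list(mci = genomes$mci,
                                reduced_a = genomes$reduced_a,
                                reduced_b = genomes$reduced_b))),
            class = "gift_scenario")
}

#' @export
print.gift_scenario <- function(x, ...) {
  cat("Synthetic scenario (seed", x$seed, "):",
      length(x$genomes$annotations), "MAGs,",
      ncol(x$abundance$counts), "metagenomic samples,",
      ncol(x$transcripts$counts), "transcriptomic samples\n")
  invisible(x)
}
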