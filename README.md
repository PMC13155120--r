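# magifts

Functional-trait analysis of genome-resolved gut microbiome data.

Microbiome studies that recover hundreds of metagenome-assembled genomes
(MAGs) need to move beyond taxonomy: the question is what each genome *can
do*, how that capacity is distributed over a community, and how both change
with host development. `magifts` implements that workflow for the kind of
study where a MAG catalogue, read-mapping counts, a phylogeny, host
phenotypes and (optionally) metatranscriptomes are available — the motivating
system being the developing caecal microbiome of broiler chickens, which
shifts from metabolically versatile generalists to genome-reduced
specialists during the first five weeks of life.

It is aimed at microbial ecologists and bioinformaticians who already have
annotation tables and count matrices (DRAM-style outputs, CoverM-style
counts) and want a tested, scriptable pipeline from those inputs to
community-level functional conclusions.

## What it computes

**Genome-inferred functional traits (GIFTs).** Each trait is a curated
pathway split into steps; a step is a set of alternative clauses, a clause a
set of jointly required gene identifiers (KEGG orthologs, EC numbers). For a
genome with identifier set *G*, a step scores

    fullness(step) = max over clauses c of |c ∩ G| / |c|

(the full / half / empty rule for two-identifier clauses), and the GIFT is
the mean of its step fullness values, in [0, 1]. The **Metabolic Capacity
Index (MCI)** of a genome is the unweighted mean of its GIFT values; genomes
are classed low (< 0.15), medium (0.15–0.30) or high (> 0.30) capacity.

**Abundances.** Cell-wise removal of read-mapping counts with breadth of
coverage < 30%, percent-mapped per sample, and

    RPMM[i,j] = counts[i,j] / (genome_length_bp[i]/1e6) / (mapped_reads[j]/1e6)

(reads per million bases of genome, per million mapped reads), plus
length-standardized relative abundances.

**Diversity.** Neutral, phylogenetic and functional Hill numbers at q = 1
(exponential-of-entropy limits; the phylogenetic form averages over branches
weighted by length and descendant abundance, the functional form is built on
Rao's quadratic entropy), and classical-scaling PCoA.

**Community traits.** Community-weighted GIFT vectors (abundance-weighted
sums of genome traits) and a scalar community MCI per sample.

**Per-taxon dynamics.** Least-squares response of log1p abundance to age or
body weight with dummy-coded covariates, classified increase / decrease /
none by case-resampling bootstrap sign support at a 0.9 threshold; the
MCI–response correlation with a permutation test; a phylogenetic
correlogram (Moran's I over patristic distance classes); and percentile
bootstrap comparisons of trait means between taxon groups with the
non-overlapping-interval evidence rule.

**Expression.** Gene-level transcript counts aggregated to per-MAG GIFT
expression profiles (TPM-style normalization; a gene feeds every trait that
lists one of its identifiers), detection of genome-reduced taxa by exact
non-transcription of the nucleic-acid biosynthesis traits B0101–B0103, and
PCoA of Hellinger-transformed profiles under Bray–Curtis dissimilarity.

**Synthetic data.** A first-class generator (`simulate_scenario()`) that
emulates all seven pipeline inputs with a planted generalist-to-specialist
succession, planted body-weight associations and planted genome-reduced
expression guilds, so every stage is testable without sequencing data. See
the methods vignette (`vignettes/magifts-methods.Rmd`) for the generative
model and every default.

## Worked example

```r
library(magifts)

db <- trait_db(list(
  gift_definition("B0211", "lysine biosynthesis",
                  list(list(c("K00928", "K00133")), list("K01714", "K00215"))),
  gift_definition("B0701", "thiamine biosynthesis",
                  list(list(c("K03147", "K00877")), list("K00946")))))
ann <- list(mag_01 = c("K00928", "K00133", "K01714", "K03147"),
            mag_02 = c("K00928", "K00946"))
gifts <- distill_catalogue(ann, db)
round(gifts, 3)
#>        B0211 B0701
#> mag_01  1.00  0.25
#> mag_02  0.25  0.50
```

`mag_01` carries both identifiers of the first lysine step and one
alternative of the second, so B0211 = (1 + 1)/2 = 1; it has one of the two
joint thiamine identifiers and not the alternative, so B0701 = (0.5 + 0)/2 =
0.25. `mag_02` holds half of step one of each pathway plus the second
thiamine step.

```r
mci_table(gifts)
#>   genome   mci capacity_class
#> 1 mag_01 0.625           high
#> 2 mag_02 0.375           high

counts <- matrix(c(1000, 4000), 2, 1,
                 dimnames = list(c("mag_01", "mag_02"), "s1"))
tab <- abundance_table(counts, matrix(1, 2, 1, dimnames = dimnames(counts)),
                       c(mag_01 = 2e6, mag_02 = 4e6),
                       c(s1 = 1e7), c(s1 = 5e6))
rpmm(tab)
#>         s1
#> mag_01 100       # 1000 / 2 Mb / 5 M mapped = 1000/2/5
#> mag_02 200
relative_abundance(tab)
#>               s1
#> mag_01 0.3333333  # length-standardized: (1000/2e6) : (4000/4e6)
#> mag_02 0.6666667

prof <- community_weighted_gifts(relative_abundance(tab), gifts)
round(prof$community_mci, 3)
#>    s1
#> 0.458              # 1/3 * 0.625 + 2/3 * 0.375
```

A full synthetic study runs end to end in seconds:

```r
sc  <- simulate_scenario(scenario_config(n_taxa = 60, n_samples_per_day = 15),
                         seed = 42)
res <- run_pipeline(sc, "out", n_boot = 200, seed = 42)
round(res$dynamics$fractions, 3)
#> increase decrease     none
#>    0.567    0.400    0.033
res$dynamics$corr[c("r", "p_value")]
#> $r
#> [1] -0.5706384
#> $p_value
#> [1] 0.001
```

Most taxa gain representation with age while the planted anticorrelation
between metabolic capacity and temporal response (here r = −0.57, permutation
p = 0.001) drives the community MCI down — the generalist-to-specialist
succession the generator encodes. `out/` holds every stage table (GIFT
matrix, RPMM, diversity, community MCI, responses, correlogram, expression,
genome-reduced flags) plus a JSON run manifest; re-running with the same
seed reproduces the files byte-identically.

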