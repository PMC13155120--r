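---
title: "Methods: trait distillation, community metrics and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait distillation, community metrics and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(magifts)
```

This vignette is the package's account of its own methods: the models and
rules it implements, the parameters that matter and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical decisions taken where the design was genuinely open.

## Trait distillation

A trait database is a catalogue of pathways ("GIFT elements") with
hierarchical codes — first character the domain (`B` biosynthesis, `D`
degradation), first three characters the function (e.g. `B02` amino-acid
biosynthesis), the full code the element (e.g. `B0211` lysine). Each element
is an ordered list of steps; each step a set of alternative clauses; each
clause a set of jointly required identifiers. The clause grammar in the
table dialect is `&` for joint requirement and `|` for alternatives, with
`|` taking scope over `&`-joined groups and no nesting. This grammar covers
the two situations that actually occur in curated pathway tables —
multi-subunit enzymes (joint) and isofunctional enzymes (alternatives) —
while whole alternative *routes* through a pathway are represented as
alternative clauses within the affected steps. That is a deliberate
simplification: a full Boolean pathway algebra would buy little for trait
scoring and would make tables much harder to curate by hand.

Scoring: a step's fullness is the best clause's fraction of present
identifiers, which reduces exactly to the full (1) / half (0.5) / empty (0)
rule for the common two-identifier clause; a GIFT is the unweighted mean of
its steps; the MCI is the unweighted mean of a genome's GIFTs. No hierarchy
weighting is applied anywhere — "averaged" means averaged. Identifiers are
matched exactly as strings; no EC-wildcard expansion is attempted, because
silent expansion makes scores depend on an external ontology snapshot and is
impossible to audit. Capacity classes cut the MCI at 0.15 and 0.30 with both
boundaries assigned to "medium", so the three classes partition [0, 1] with
the open intervals below 0.15 and above 0.30 matching the conventional
reading of "low (<0.15)" and "high (>0.30)" capacity classes.

The package ships a study-scale database of 170 elements
(`study_trait_db()`). Its content is synthetic — constructed to the
cardinality and code structure of the curated distillR-style catalogue, with
the elements that the analyses name (B0101–B0103, B0211, B0401–B0403, B0701,
B0805, D0509) present under their conventional meanings — and it is labelled
synthetic in its file names. It exercises every parsing and distillation
contract at full scale; it carries no curated biology.

## Abundance normalization

Read-mapping counts are filtered cell-wise: a MAG's counts in a sample are
zeroed when its breadth of coverage there is strictly below 0.30. The filter
is per cell, not per MAG, because spurious cross-mapping is a per-sample
phenomenon. Percent-mapped is retained counts over total read pairs × 100.

RPMM divides counts by genome length in Mb and by the sample's
catalogue-mapped read pairs in millions. The second divisor is the mapped
total — that is what makes RPMM invariant to sequencing effort and is what
the unit's name says ("per million mapped reads"); a fixed nominal read
length would not remove effort differences between samples. Relative
abundances standardize counts by genome length and renormalize each sample
to 1. Samples that end up empty (everything filtered) are reported as
missing and excluded from diversity with a warning, rather than failing a
whole batch for one degenerate sample.

## Hill-number diversity at q = 1

All three components use the analytic q → 1 limit (exponentials of entropy
forms), never a plug-in at q = 1, which is undefined. The neutral form is
`exp(-Σ p log p)`. The phylogenetic form is the mean-effective-lineages
form: branch abundances are tip-proportion sums over descendants, branches
are weighted by length relative to the abundance-weighted tree depth. On a
star tree with equal branch lengths it reduces to the neutral form, which
the tests exploit as an identity. The functional form is built on Rao's
quadratic entropy Q and is invariant to rescaling the trait distance matrix;
two maximally distinct taxa at equal abundance give 4 (effective *pairs*
square the effective number of taxa). A community in which all abundant taxa
are functionally identical has Q = 0 and no defined functional diversity;
that is reported as a degenerate-input error, not silently as 1. Functional
distances default to Euclidean distances on the trait matrix, matching the
trait-space ordination; the distance is a parameter because trait matrices
of different provenance (element-level GIFTs vs. module fullness) are all
legitimate inputs.

PCoA is classical scaling: double-centred squared dissimilarities,
eigendecomposition, axes scaled by the square roots of positive eigenvalues.
Negative eigenvalues (possible under Bray–Curtis) are reported and their
axes dropped.

## Per-taxon dynamics

The joint hierarchical species model that motivates this module is out of
scope by design; the package substitutes a per-taxon procedure with the same
reporting contract. Each taxon's transformed abundance (log1p of RPMM —
strictly monotone, defined at zero) is regressed on the predictor (age in
days, or body weight in g at the final day) plus dummy-coded fixed
covariates (trial, sex, line, treatment; pen effects are deliberately not
modelled — with cross-sectional sampling a pen random effect is nearly
confounded with the residual and would buy fragility). Direction is
classified by case-resampling bootstrap sign support: the fraction of
bootstrap slopes sharing the better-supported sign, against a threshold of
0.9 — the support level used to report increasing/decreasing taxa.

The calibration of that rule should be understood before interpreting the
fractions: sign support ≈ Φ(|t|), so support ≥ 0.9 corresponds to |t| ≳
1.28, and a truly null taxon is called in *some* direction about 20% of the
time (about 10% per sign). The threshold is a reporting convention tuned for
sensitivity, not a 5% test; the test suite asserts this null behaviour
rather than pretending otherwise. All bootstrap and permutation procedures
take explicit seeds and are bit-identically reproducible.

The MCI–response correlation is Pearson's r with a two-sided permutation
p-value (999 label permutations, +1-corrected). The phylogenetic correlogram
bins patristic distances into equal-frequency classes and computes binary-
weight Moran's I per class against the null expectation −1/(n−1); if all
pairwise distances coincide (two tips), a single class is formed. Group
comparisons use percentile bootstrap intervals of group means with the
non-overlap evidence rule; percentile intervals at n = 30 undercover
mildly (coverage near 93–94% at a nominal 95%), which the acceptance script
measures rather than hides.

## Expression profiling

Transcript counts are normalized TPM-style (per-kb rate, sample rescaled to
1e6). A gene contributes its expression to every element listing one of its
identifiers; the default per-MAG profile is the abundance-weighted *sum*
over contributing genes, because expression heatmaps are graded — a
pathway's transcription level, not its completeness, is the signal. The
alternative `mode = "fullness"`, scoring pathway completeness over the set
of expressed identifiers, is provided for analyses that want capacity-style
values from expression. Both raw and per-sample-normalized attributions are
available; genome-reduction detection uses raw counts only, with an exact
zero over B0101–B0103 as the criterion — "lack of transcription" is an
absolute statement, and any depth threshold would turn it into a
depth-dependent one. Genomes absent from the transcript table are flagged
with an explicit no-data caveat instead of being silently treated as
non-transcribing. Expression ordination Hellinger-transforms profiles and
applies Bray–Curtis before PCoA.

## The synthetic study

`scenario_config()` fixes the emulated study conditions; `simulate_scenario()`
derives sub-seeds from one seed and produces all seven inputs.

*Design.* Three cross-sectional sampling days (7, 21, 35) with 40 animals
per day by default (120 animals), two trials, two sexes, two genetic lines,
three treatments, 24 pens; body weight baselines 180 / 950 / 2200 g follow
typical broiler growth. Per-sample depth is lognormal around 2 M read
pairs, and the fraction of a sample's reads mapping to the catalogue is
drawn around 0.67 (sd 0.06), the level reported for deeply sequenced caecal
catalogues.

*Genomes.* A gene-retention probability evolves as Brownian motion on the
logit scale along a Yule tree (base retention 0.40, rate 1.5) — the
generalist–specialist gradient. Genomes keep each pathway identifier
independently with their retention probability; genome length is 1.2 Mb +
9 kb per retained pathway gene + Gaussian noise, so length and MCI are
positively coupled as observed in real catalogues. Two genome-reduced
guilds are planted from the lowest-retention taxa: both lack all
nucleic-acid biosynthesis genes; guild A carries complete SCFA, thiamine,
lysine, indole-3-acetate and arginine-degradation pathways, guild B only
SCFA and thiamine. Every non-reduced genome keeps at least one identifier
of each of B0101–B0103 so its transcription is observable.

*Succession.* Per-taxon log-abundance is intercept + slope × day plus
N(0, 0.6) sample noise, mapped through a softmax to multinomial proportions.
Intercepts correlate 0.8 with MCI (generalists dominate the early
community) and the slope's non-capacity component reverts the intercept's
non-capacity component (reversion 0.9), while the slope–MCI correlation is
held at the configured −0.6 exactly by construction. The intercept sd of
2.2 was chosen so that the log-abundance variance contracts between day 7
and day 35 (the condition σ_int·|ρ_int,slope| > (35+7)/2 · σ_slope with
σ_slope = 0.08): evenness and hence all diversity metrics rise with age,
the early dominants decline, most taxa rise in relative terms, and the
community-weighted MCI falls — the four qualitative signatures of the
emulated succession, arising from one mechanism rather than four dials.

Because count data are compositional, only responses *relative to the
community* are identifiable; the planted per-taxon slopes are log-scale
trends whose observable counterparts are shifted by a common community
term. That shift is the same for every taxon within a sample, so the
MCI–slope correlation is unaffected — which is why that correlation, not
the raw fraction of increasing taxa, is the generator's calibrated target.

*Body weight.* Weight is the day's baseline plus planted effects on
standardized relative abundances: few strong positive taxa (default 2 of
150, drawn from guild A when detectable; effect 2 × noise sd each) and many
diffuse negative taxa (35 of 150, guild B plus the highest-capacity eligible
taxa; 0.4 × noise sd each), plus N(0, 150 g) noise, all scaled by the day's
baseline so early-life weights stay positive. The 2:35 split scales a
10:190 association split of an 822-genome catalogue to the default size. Planted
taxa are restricted to taxa whose breadth clears the coverage filter in at
least 80% of final-day samples — associations are planted among taxa the
analysis can observe, as is true of any reported association. An optional
`diversity_effect` adds a direct negative diversity–weight dependence for
scenarios that need it; it is 0 by default so taxon effects are not
confounded.

*Transcripts.* One gene per retained identifier; active genes (guild gene
sets for the planted guilds, the full repertoire otherwise) get negative-
binomial counts (per-gene lognormal activity around mean 5, dispersion
size 2, lognormal per-sample depth factors) across 10 samples; inactive
genes are present with zero counts.

*What the generator does not emulate.* No read-level data or sequence
content; no phylogenetic correlation in the dynamics *residuals* (phylogeny
enters through the retention gradient only, so correlogram signal on
generator output comes from the capacity gradient); no longitudinal
repeated measures (animals are sampled once, as in the emulated design); no
pen, maternal or cage effects on abundances; no taxon–taxon interactions
beyond compositional coupling. Passing recovery tests on this generator
therefore shows the pipeline correctly extracts structure *of the planted
kinds* at realistic noise levels — it does not certify behaviour under,
e.g., strong phylogenetically structured residual covariance.

## Problem sizes and reproducibility

The shipped tests run the default scenario (150 taxa, 40 GIFT elements, 120
metagenomic samples, 10 transcriptomic samples) across 20 seeds for the
recovery checks, 5 seeds for genome-reduction false-flag rates, and use 200–
2000 bootstrap replicates depending on the statistic; these sizes give
stable Monte-Carlo estimates of every planted quantity while keeping a full
test run in minutes on one CPU. Every stochastic entry point takes an
explicit seed, restores the caller's RNG state, and reproduces its output
bit-identically; the pipeline writes a JSON manifest whose config hash
changes exactly when a configurable value changes.

## Known limitations

The per-taxon bootstrap stand-in ignores cross-taxon covariance and
phylogenetic signal in residuals, so its support values are not posterior
probabilities and its per-sign null call rate is ~10% at the 0.9 threshold
(see above). Dual-identifier half-credit makes GIFT values step-wise, not
continuous, for short pathways. The functional-diversity error at Q = 0
means single-taxon communities have no defined functional diversity.
Percentile bootstrap intervals undercover slightly at small n. The 170-
element database is structural, not curated.
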