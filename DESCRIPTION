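Package: magifts
Title: Genome-Inferred Functional Traits and Community Metabolic Capacity for
    Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distills per-genome gene annotations into quantitative
    genome-inferred functional traits (GIFTs) scored as pathway fullness in
    [0,1], summarises them as a Metabolic Capacity Index (MCI) per genome and
    per community, normalises metagenome-assembled genome (MAG) read counts
    into length- and depth-corrected abundances (RPMM), computes neutral,
    phylogenetic and functional Hill-number diversities at q = 1, classifies
    per-taxon temporal and body-weight responses with a bootstrap
    sign-support rule, aggregates metatranscriptomic gene counts into GIFT
    expression profiles and flags genome-reduced taxa by non-transcription of
    nucleic-acid biosynthesis pathways. Ships a synthetic-data generator that
    emulates a generalist-to-specialist gut-community succession so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
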