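Package: reshufflr
Title: Recombination Landscapes, Genome-Wide Reshuffling and Diversity
    Across Divergent Karyotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how chromosomal fissions and fusions
    reshape the recombination landscape of holocentric genomes.  Reads
    karyotype and Marey-map (linkage map) tables, estimates windowed
    recombination rates with physical-distance weighting, decomposes the
    genome-wide probability of pairwise reshuffling (r-bar) into its
    interchromosomal (independent assortment) and intrachromosomal
    (crossover) components with the Kosambi map function, computes
    pixy-style windowed nucleotide diversity from allele counts that
    include invariant sites, classifies 0-fold and 4-fold degenerate
    coding positions, and fits permutation-tested regressions of
    diversity ratios on recombination-rate ratios over ancestral
    chromosome blocks.  A seeded synthetic-data generator (karyotype
    rearrangement, interfering crossovers, pedigree gametes, diversity
    landscapes with planted effects) makes every stage of the pipeline
    verifiable without pedigree or resequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
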