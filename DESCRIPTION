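Package: phylogeocat
Title: Comparative mtDNA Phylogeography and Climate-Envelope Niche Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparative phylogeography from aligned mitochondrial
    DNA: haplotype collapsing and polymorphism summaries, gene and nucleotide
    diversity, Tajima's D and Fu's Fs neutrality tests with coalescent
    p-values, mismatch distributions with sudden-expansion model fitting and
    mutation-rate-calibrated expansion dating, AMOVA-based Phi-ST with
    permutation tests under alternative population groupings, Mantel tests of
    isolation by distance, median-joining haplotype networks, neighbour-joining
    trees with bootstrap support, and a BIOCLIM percentile-envelope species
    distribution model with replicate AUC evaluation. Includes coalescent and
    climate-raster simulators so every stage is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
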