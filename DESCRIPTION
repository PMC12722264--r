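Package: selmap
Title: Population Structure and Selection Mapping for SNP Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for population-genomic analysis of SNP array
    genotypes across related livestock populations: PLINK binary input and
    output, tiered quality control, VanRaden genomic relationship matrix and
    principal components, observed and expected heterozygosity, allele-sharing
    distances, Weir-Cockerham fixation index, identity-by-state neighbor-joining
    trees, linkage-disequilibrium decay, cross-population consistency of
    gametic phase, sliding-window detection of runs of homozygosity with island
    calling, generation-proxy selection mapping (a mixed-model genome scan with
    birth year as the response), and hypergeometric QTL-category enrichment of
    windowed markers. A multi-population genotype simulator with known
    divergence, linkage disequilibrium, autozygosity, and temporal
    allele-frequency trends makes every stage testable without proprietary
    breed-association data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
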