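Package: panelkin
Title: Genome-Wide Placement of a Resequenced Accession Against a
    SNP-Chip Germplasm Panel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares a low-coverage whole-genome-resequenced crop
    accession against a chip-genotyped germplasm panel. Array probes are
    placed on the consensus genome by exact k-mer seeding with ungapped
    full-length extension, SNP offsets are projected into genome
    coordinates, chip-orientation genotypes are extracted and concatenated
    into per-accession pseudomolecules, and accessions are related by
    pairwise-deletion p-distances, neighbor-joining trees with
    locus-resampling bootstrap supports, and identity-by-state duplicate
    detection with missingness, heterozygosity, Hardy-Weinberg and
    LD-pruning filters. A principal component analysis of standardized
    morphological descriptor tables supports phenotypic placement. Seeded
    simulators generate genomes, probe sets, genotype panels and
    descriptor tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    callr,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
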