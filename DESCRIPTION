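Package: popconnect
Title: Multi-Marker Population Structure and Connectivity for Abyssal Bivalves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-track population-structure pipeline for deep-sea
    invertebrates sampled across ocean basins. Track one delimits
    mitochondrial lineage clusters (mitotypes) from aligned COI/16S
    fragments via substitution counts, Kimura-2-parameter distances and
    minimum-spanning haplotype networks, accommodating the deeply diverged
    F/M lineages produced by doubly uniparental mitochondrial inheritance.
    Track two infers genome-wide structure from SNP genotypes: missingness
    and singleton filtering, linkage-disequilibrium pruning, sparse
    nonnegative matrix factorization admixture with masked cross-entropy
    validation, replicate-run summaries with label alignment and
    Gelman-Rubin/effective-sample-size diagnostics, Nei distances,
    Nei-Chesser corrected F_ST and Ward/DAPC clustering. Track three
    processes MALDI-TOF proteomic fingerprints (square-root transform,
    Savitzky-Golay smoothing, SNIP baseline, TIC normalization, peak
    detection, strict binning, Hellinger transform) through hierarchical
    clustering and random-forest classification. Synthetic-data generators
    with known truth make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    MASS,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
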