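Package: beemito
Title: Mitotype Classification and Diversity Analysis for the Honey Bee
    tRNAleu-cox2 Intergenic Region
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for maternal-lineage diagnostics of Apis mellifera from
    the hypervariable tRNAleu-cox2 mitochondrial intergenic region. Locates
    the P and Q elements and DraI (TTTAAA) restriction sites in amplicon
    sequences, classifies evolutionary lineages (A, M, C, Y) and African
    sub-lineages (AI, AII, AIII, Z), calls named haplotypes and novel
    variants against an encoded reference catalog, and summarises
    populations with per-site diversity statistics (Na, Ne, Np, unbiased
    haplotype diversity), AMOVA-based PhiPT differentiation with
    permutation tests, principal coordinate analysis, bootstrapped
    neighbor-joining trees and median-joining haplotype networks. Includes
    a synthetic amplicon generator implementing the element grammar of the
    region so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
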