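Package: mullerx
Title: Muller Element Homology and Sex-Chromosome Turnover in Flies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of dipteran karyotype evolution
    from cross-species gene-mapping tables. Assigns chromosomes to the six
    conserved Muller elements by shared-gene enrichment (expected-count model
    plus Fisher's exact test), classifies sex-chromosome events (ancestral X,
    X-autosome fusions, turnovers and element-F reversals), fits single- and
    multi-regime two-state Markov models of turnover on a phylogeny with
    likelihood-ratio comparison, reconstructs ancestral gene content of the
    dot chromosome under Brownian motion, computes windowed GC content for
    X-versus-autosome contrasts, and infers inter-chromosomal gene movement
    from species trios against a size-weighted expectation null with
    chi-square testing and expression follow-up. A synthetic-data generator
    with full ground truth supports end-to-end validation of every stage.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
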