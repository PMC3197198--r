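Package: scatyper
Title: Gene-Centric Strain Typing of Rumen Cellulolytic Bacteria from scaC
    Clone Libraries and T-RFLP Community Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for gene-centric surveys of intraspecific diversity in
    rumen microbial communities, built around the small scaffoldin gene scaC
    of Ruminococcus flavefaciens as a strain-level marker. Implements
    terminal restriction fragment length polymorphism (T-RFLP) profile
    normalization with a fluorescence detection cutoff, in-silico restriction
    digests of degenerate-primer amplicons with terminal-fragment prediction
    and multi-enzyme fragment-to-taxon assignment, from-first-principles
    Bray-Curtis dissimilarity, Kruskal non-metric multidimensional scaling,
    one-way and pairwise ANOSIM permutation tests and SIMPER decomposition,
    FastGroup-style greedy percent-identity clustering of clone libraries
    with Chao1, Shannon-Wiener and analytic rarefaction estimators, and
    detection of the duplicated 22-residue dockerin repeat in translated
    scaffoldin sequences. A synthetic-community generator with controllable
    animal, fraction and week effects makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    vegan,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
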