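Package: bacafinder
Title: Classification of SbmA/BacA and BclA Antimicrobial Peptide
    Transporter Homologues from HMM, Network and Phylogenetic Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and classifies bacterial SbmA/BacA and BclA
    antimicrobial-peptide-transporter homologues across proteomes by
    reconciling three evidence streams: profile hidden Markov model
    annotation, a sequence similarity network built from Smith-Waterman
    alignment scores with Karlin-Altschul statistics, and clade membership
    in a neighbour-joining protein phylogeny rooted on outgroup families.
    Includes a rule engine that merges the evidence into final
    SbmA/BacA, BclA or excluded calls, per-taxon distribution summaries,
    and a synthetic-benchmark generator (species tree, gene gain/loss/HGT,
    profile-emitted family sequences, decoys) with recovery scoring so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    methods,
    phangorn,
    phytools,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
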