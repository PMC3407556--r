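Package: pseudophy
Title: Detection and Phylogenetic Mapping of Gene-Inactivating Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects inactivating (pseudogenizing) mutations -- frameshift
    insertions, frameshift deletions and nonsense substitutions -- in codon
    alignments carrying an intact reference taxon, and locates the premature
    stop codon each mutation introduces. Infers maximum-likelihood phylogenies
    under nucleotide substitution models up to HKY85 with discrete-gamma rate
    variation (Felsenstein pruning in compiled code), selects the model by AIC,
    computes nonparametric bootstrap supports, and roots with a designated
    outgroup while coding indels and nonsense codons as missing data. Each
    mutation is then placed on the ancestral branch where it arose under a
    single-origin (Dollo) assumption and events are partially ordered along
    lineages. A codon-alignment simulator with planted mutation events,
    including a canonical 14-taxon fixture emulating Tas1r1 exon-3
    pseudogenization in pinnipeds, supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    seqinr,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
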