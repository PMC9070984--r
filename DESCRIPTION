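Package: phagewo
Title: Typing, Horizontal Transfer and Intragenic Recombination of Bacteriophage WO
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for bacteriophage WO marker-gene (orf7)
    diversity in Wolbachia-infected insects. Flags orf7 pseudogenes by
    internal stop codons, computes Kimura two-parameter distances with
    pairwise deletion, clusters functional sequences into phage WO types at
    a 1.5 percent divergence threshold, enumerates horizontal-transfer
    events as phage types shared across distinct Wolbachia strains and
    supergroups, detects intragenic recombination with five statistics
    (MaxChi, Chimaera, a 3Seq-style walk, a GENECONV-style run scan and
    BootScan) under seeded permutation nulls with a multi-method consensus
    rule and breakpoint estimation, and summarises phage/symbiont
    phylogenetic incongruence from bootstrap neighbor-joining trees. A
    seeded synthetic-data generator plants types, transfers, recombinants
    and pseudogenes with a machine-readable truth record so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
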