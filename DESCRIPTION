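Package: chsfam
Title: Classification and Evolutionary Profiling of Fungal Chitin Synthase Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for surveying chitin synthase (CHS) gene
    families across fungal proteomes: candidate screening against
    characteristic Pfam domains and the conserved CON1 catalytic motifs
    (QxxEY, EDRxL, QxRRW), motif-anchored extraction of the CON1 region,
    domain-architecture typing (Groups A/B, Types A1-A3 and B1-B4),
    reference-guided phylogenetic class assignment (Classes I-VII and the
    basal CHS23b group) by neighbor-joining with bootstrap, per-taxon
    family expansion and contraction profiles, and detection of the
    head-to-head ChsV/ChsVII chromosomal arrangement. Includes a
    class-structured synthetic proteome simulator so every stage is
    testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
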