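Package: kinventory
Title: Genome-Wide Inventory of Potassium Transporter Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for building plant K+ transporter
    gene-family inventories. Screens a proteome with degenerate
    family-specific protein motifs, curates candidates by outermost-motif
    span and annotates them with physicochemical properties (length,
    molecular weight, isoelectric point, transmembrane-segment count);
    assigns clades by neighbor joining against reference anchors; classifies
    paralog pairs as tandem or segmental duplicates and dates duplication
    events from synonymous divergence (Nei-Gojobori Ks, T = Ks/2*lambda);
    detects conserved exon structures from gene models; clusters orthologs
    at an identity threshold; and builds per-clade expression models from
    TPM matrices. Ships seed-deterministic synthetic-data generators with
    planted ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
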