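Package: tsepipe
Title: Comparative Floral Transcriptome Annotation, Expression and
    Lineage Analysis with Ground-Truthed Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for comparative analysis of de novo
    (454-style) floral transcriptomes: annotation of contigs against a
    reference proteome by reciprocal best bidirectional hits, flagging of
    chimeric contigs, expression quantification by single-best-hit read
    counting with RPKM normalisation under two reference strategies
    (reads mapped to orthologous reference CDS, TSE1, or to the de novo
    contigs themselves, TSE2), rarefaction-based sequencing-saturation
    analysis, detection of lineage-specific genes across five rosid taxa
    with Dollo gain/loss interpretation, qualitative presence/absence
    comparison against a microarray-defined transcriptome, and
    validation of in silico expression against qPCR via standard-curve
    efficiencies and the comparative Cq (delta-delta-Cq) method. A
    synthetic-data module generates read libraries, reference CDS sets
    with planted cross-taxon presence/absence structure, contigs with
    UTR padding and chimeras, noisy similarity-hit tables and dilution
    series Cq data with a complete ground-truth ledger, so that every
    stage of the pipeline can be benchmarked against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
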