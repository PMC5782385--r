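Package: splicescape
Title: Alternative Splicing Event Detection and Differential Splicing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies alternative splicing events (intron
    retention, exon skipping, alternative acceptor and donor sites) from
    transcript models in GTF, calibrates an empirical FPKM expression cutoff
    against decoy transcripts, filters isoforms by replicate-concordant
    expression, tests event-level differential splicing between conditions
    with Fisher's exact test and a change-frequency statistic, characterises
    event lengths and reading-frame preservation, and summarises group
    presence and overlap. Ships a synthetic transcriptome generator with
    known ground truth so the full pipeline is testable without external
    data. Designed around a salt-stress study layout of two tissues, two
    conditions, five timepoints and two replicates, but usable for any
    comparable replicated design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
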