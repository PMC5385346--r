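Package: xdosage
Title: X-Chromosome Dosage Analysis for Sexed Blastocyst Transcriptomes
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify X-chromosome dosage from gene-level FPKM
    expression matrices of sexed preimplantation embryos and somatic donor
    cells. Computes female-to-male expression ratio distributions of
    X-linked genes, per-sample X-to-autosome (X:A) expression ratios,
    megabase sliding-window chromosome expression profiles, sex-differential
    expression with X-linked/autosomal partitioning, k-means trajectory
    clustering across reprogramming states, and paired inner-cell-mass
    versus trophectoderm lineage comparisons. Includes a calibrated
    synthetic-data generator emulating the statistical structure of sexed
    bovine blastocyst transcriptomes so every stage of the analysis can be
    exercised and validated without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    pheatmap
Config/testthat/edition: 3
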