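Package: ribopause
Title: Codon-Level Pause-Score Analysis of Ribosome Profiling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ribosome pausing from Ribo-seq, Disome-seq and
    RNA-seq data at codon resolution. Builds 3'-end-aligned per-nucleotide
    occupancy tracks in rpm units, computes site-level and motif-averaged pause
    scores for every tri-amino-acid motif occupying the ribosomal E, P and A
    sites, compares conditions to identify stress-induced ("redox") pausing
    motifs, produces motif-aligned metaprofiles and start/stop metagenes, and
    quantitates gene-level translation (rpkm, translation efficiency). Includes
    a synthetic footprint simulator with planted multiplicative pauses, a toy
    exact-match aligner, UMI-based PCR-duplicate removal, and an end-to-end
    pipeline driver, so every statistic can be validated against a known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
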