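Package: divorseq
Title: Genome-Wide Transcription Factor Off-Rate Estimation from Depletion ChIP-Seq Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates in vivo off-rates and mean residence times of
    DNA-binding proteins from ChIP-seq time courses acquired during nuclear
    depletion (anchor-away). Provides fragment-midpoint coverage
    quantification, background-fraction normalization, per-site first-order
    exponential decay fitting with pseudo-R-squared goodness of fit,
    residence-time quartile classification, peak filtering by fold enrichment
    and motif composition (including the G/C at -8 bp cross-linkability
    rule), position-weight-matrix scanning, and residence-time-stratified
    chromatin metrics (MNase protection ratio, nucleosome-free region width,
    RNA polymerase II roadblock index) together with nascent-RNA
    synthesis-decay analysis. A seeded synthetic-data generator produces
    every input format the pipeline consumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
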