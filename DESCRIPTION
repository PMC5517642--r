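Package: srnaspike
Title: Design and Use of Small RNA Spike-In Oligonucleotides for Absolute
    Normalization of sRNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design genome-excluded, structure-matched small RNA
    spike-in oligonucleotide sets and to use them, together with poly(A)
    (ERCC) spike-ins, to convert relative small RNA sequencing read counts
    (reads per million genome-matching reads, RPM) and mRNA-Seq transcript
    abundances (TPM) into absolute molecules per microgram of total RNA
    (MPU). Includes a perfect-match, multi-mapping-aware read quantification
    pipeline, small RNA class and family aggregation, log-linear spike-in
    standard curves, relative-versus-absolute comparison statistics,
    sRNA:precursor and sRNA:target stoichiometry summaries, and a synthetic
    data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
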