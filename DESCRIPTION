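Package: regland
Title: Environment-Dependent Reg-Seq Analysis of Bacterial Promoters
Version: 0.1.0
Authors@R:
    person("regland", "developers", email = "regland@example.org",
           role = c("aut", "cre"))
Description: A pipeline for massively parallel reporter assay (MPRA)
    footprinting of bacterial promoters across growth conditions: design of
    mutagenized promoter libraries with barcode scaffolding, a
    statistical-mechanics (thermodynamic occupancy) simulator that generates
    ground-truth synthetic datasets, barcode-to-variant count processing,
    per-base mutual-information footprints and expression-shift matrices,
    automated footprint classification by coefficient-of-variation response
    to Gaussian smoothing, two-state hidden Markov model segmentation of
    footprints into activator- and repressor-like binding sites, detection
    of emergent transcription start sites created by single mutations that
    complete the sigma-70 minus-10 element, and hierarchical clustering of
    growth conditions by regulatory response.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
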