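Package: epibin
Title: Epitope Binning of Displayed Antibodies by Competitive Sorting and
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for sequencing-based epitope
    binning of antibody libraries displayed on antigen-expressing cells.
    Models single-cell competitive binding between displayed query scFvs and
    fluorescently labelled reference antibodies under mass-action
    equilibrium, simulates flow-cytometry gating and sorting of the
    reference-antibody-non-binding population, generates barcoded
    single-end amplicon reads from pre- and post-sort clone pools, and
    processes reads (sliding-window quality trimming, primer matching,
    barcode demultiplexing, translation, exact-window clone assignment)
    into count tables. Clones are classified into epitope bins from
    negative-control-normalised enrichment ratios, and saturation-binding
    titrations can be fitted to recover dissociation constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    optparse
Config/testthat/edition: 3
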