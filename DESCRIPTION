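Package: rollseq
Title: Concatemer-Based Fidelity Analysis of RNA Polymerases and Reverse
    Transcriptases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of long concatemeric cDNA reads produced by
    rolling-circle reverse transcription of a circular RNA template.
    Reads are segmented into individual full-length template copies
    (concatemers), each copy is globally aligned to the template and
    left-normalized variants are called, and every variant is attributed
    to the RNA polymerase (present in every concatemer of a molecule) or
    to the reverse transcriptase (private to a single concatemer).
    Per-enzyme substitution, insertion and deletion rates are estimated
    with uncertainty, together with substitution spectra,
    transition/transversion breakdowns and positional indel profiles.
    A seeded simulator generates reads with planted, labelled errors so
    every stage is testable without sequencing data, and a companion
    strand-versus-strand module measures second-strand synthesis
    fidelity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
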