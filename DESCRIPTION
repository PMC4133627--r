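Package: ProfileRealign
Title: Profile-Based Meta-Alignment Refinement of Nucleotide Multiple
    Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Takes an existing DNA/RNA multiple sequence alignment,
    summarizes it into a count-weighted (non-probabilistic) profile,
    independently realigns every sequence against that profile with a
    Gotoh affine-gap dynamic program using position-specific gap-opening
    penalties, and merges the individual sequence-profile alignments into
    a reformed alignment, iterating until the alignment is stable.
    Includes alignment accuracy metrics (sum-of-pairs/developer, modeler
    and total-column scores), a synthetic sequence-family simulator with
    known true alignments for validation, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
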