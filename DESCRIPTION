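Package: bsalign3
Title: Three-Letter Bisulfite Read Alignment, Methylation Calling and QC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for whole-genome bisulfite sequencing
    (WGBS) data. Builds a single hash-style seed index over the C-to-T
    converted concatenation of the Watson and Crick strands of a reference
    genome, aligns in-silico converted reads by seed-and-extend with a banded
    (Ukkonen) edit-distance kernel, re-counts mismatches bisulfite-aware in
    the original base space with randomized early termination, calls
    per-cytosine methylation in CG/CHG/CHH contexts to CGmap output, and
    provides post-alignment QC (per-cycle mismatch profile, lambda spike-in
    conversion efficiency, genome-wide methylation windows, metagene
    profiles). Includes a bisulfite read simulator with ground-truth ledger
    and a mapping-accuracy evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
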