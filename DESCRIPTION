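Package: racemap
Title: 3'-RACE End Mapping and Isoform Quantification for Single-Gene
    Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps templated 3'-end coordinates of a single-gene transcript
    from RNA ligase-mediated 3'-RACE deep-sequencing reads, calls
    non-templated nucleotide additions (oligo-adenosine tails), collapses
    PCR duplicates with 10-nt molecular barcodes, tallies 3'-end isoform
    distributions (mature, 3'-extended short, 3'-extended long), and
    compares knockdown against control libraries. Includes a synthetic
    RLM-RACE read simulator with per-molecule ground truth, and gel
    time-course quantification: loading-control and t0 normalization,
    50%-decay time by log-linear interpolation, and fold-change testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
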