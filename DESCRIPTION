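Package: polyoccu
Title: Polysome Profiling and Polysomal Occupancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of sucrose density gradient A254 traces (baseline
    subtraction, area under the curve, polysomal-area percentages and
    fraction pooling), three-contrast differential analysis of steady-state
    mRNA level, polysomal mRNA level and polysomal occupancy with
    Benjamini-Hochberg correction and a fold-change/significance call rule,
    fraction-resolved ribosome-density metrics with mechanistic scenario
    classification, transcript sequence features (region lengths, GC content,
    effective number of codons, upstream open reading frames, start-codon
    context) with rank-based target-versus-background comparisons, and
    degenerate-consensus motif enrichment by one-tailed Fisher tests.
    Includes a two-pool stochastic ribosome-loading simulator that generates
    gradient traces, fraction profiles, expression matrices and transcript
    sequences with known ground truth, so every stage of the pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
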