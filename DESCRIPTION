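Package: flexscan
Title: Homolog Screening by Intrinsic Disorder Content and Hybrid FLEX Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens homologs of a query protein for intrinsic structural
    order to support rational expression-construct design. Runs a local
    homology search with Karlin-Altschul E-value statistics against a FASTA
    library, predicts per-residue intrinsic disorder through a pluggable
    predictor interface, computes the intrinsic disorder score (IDS, the
    percentage of residues above a disorder threshold) and the hybrid FLEX
    score (a weighted average of a hyperbolic E-value transform and the
    intrinsic order), virtually processes viral polyprotein hits into mature
    chains, and projects disorder traces onto a progressive multiple sequence
    alignment for comparative analysis of disorder conservation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse,
    jsonlite
Config/testthat/edition: 3
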