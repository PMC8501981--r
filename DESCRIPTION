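Package: nascycle
Title: Natural Antisense Transcript Control of Cell-Cycle Inheritance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative model of transgenerational cell-cycle coordination
    by a natural antisense transcript (nAS25) of the notch-1 locus. Couples a
    phase-gated transcript-fate model (antisense masking, C-to-U hyper-editing,
    premature termination codons, nonsense-mediated decay) to a stochastic
    cell-lineage simulator in which inherited antisense titer sets daughter
    G1-phase duration. Includes the companion analysis computations: delta-Ct
    normalization of locus distribution across DNA supercoiling zones with a
    permutation shift test, exon-pair secondary-structure propensity z-scores
    via a Nussinov base-pairing score, and cumulative mitotic-rate statistics
    (least-squares rates, fold changes, deviation-from-linearity breakpoints).
    All inputs are produced by a seeded synthetic-data module, so the full
    pipeline runs without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
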