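Package: SEcomm
Title: Shrink/Expand Scoring of Cell-Cell Communication Changes Between
    Biological States
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies directional change in inferred cell-cell
    communication (CCC) between two biological states from ligand-receptor
    (LR) inference tables such as LIANA consensus output. Implements the
    Shrink/Expand (SE) score, a bounded directional set-similarity metric
    over per-communication-type LR sets; Consensus/Gain/Potential-Loss
    classification of CCC inference units with gain and potential-loss
    ratios; organ-level aggregation of SE scores; Wilcoxon signed-rank
    consensus-shift testing on interaction magnitudes; two-cluster molecule
    shortlisting; frequency-based ranking of LR pairs with single-molecule
    decomposition; and a seeded permutation null for non-stochastic
    categorical change. Ships a synthetic-data generator with planted
    ground truth and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
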