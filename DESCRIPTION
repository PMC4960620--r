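Package: adderfpt
Title: First-Passage-Time Models of Bacterial Cell-Size Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic stochastic modelling of the adder principle of
    bacterial cell-size homeostasis. A timekeeper protein is expressed in
    random bursts at a rate proportional to the exponentially growing cell
    volume, and division fires when its copy number first reaches a
    threshold. The package provides the analytic burst-count, division-time
    and added-volume distributions and moments of this first-passage model,
    exact stochastic simulation of single cycles, multi-generation lineages
    and a replication-initiation variant, four deviation-from-adder
    mechanisms, and statistical utilities (size binning, bootstrap CV2
    confidence intervals, Kolmogorov-Smirnov collapse diagnostics and
    permutation trend tests) for simulated or user-supplied single-cell
    lineage tables.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
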