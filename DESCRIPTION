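Package: cmcs
Title: Constrained Minimal Cut Sets for Strongly Growth-Coupled Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decides, for constraint-based metabolic models, whether the
    production of a metabolite can be strongly coupled to growth, by computing
    and verifying constrained minimal cut sets (reaction or gene knockouts)
    with a duality-based mixed-integer linear program. Provides flux balance
    and flux variability analysis primitives, lossless network compression
    (conservation relations, fully coupled reaction sets), integration of
    gene-protein-reaction rules for gene-level knockouts, a batch screening
    driver that classifies every substrate-producible organic metabolite as
    coupleable, provably not coupleable, or undecided at given minimum-yield
    levels, and a small-network fixture generator with an exhaustive
    brute-force oracle. Linear and mixed-integer programs are solved with the
    HiGHS solver through a persistent Python/SciPy worker process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with scipy on the PATH
Imports:
    tools,
    jsonlite,
    Matrix,
    methods,
    processx,
    stats,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
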