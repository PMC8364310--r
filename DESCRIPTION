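Package: ddis
Title: Data-Driven Iterative Searching for Tau-Associated White-Matter Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a data-driven iterative searching (DDIS) analysis linking
    gray-matter tau-PET signal to white-matter diffusion metrics along structural
    connections. Builds a group-common binary connectivity backbone from per-subject
    streamline-count matrices, calls regional tau positivity and prevalence, selects
    high-prevalence seed regions, and iteratively propagates a dual linear-regression
    test (seed tau to edge diffusion metric; edge diffusion metric to destination tau)
    over the backbone until no further association pathways are found. Stability of
    the discovered pattern is assessed by bootstrap resampling of subjects with a
    voting summary. A synthetic-cohort generator with planted node-edge-node
    association chains, covariate confounding, and noisy spurious connections
    provides tested ground-truth data for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
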