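Package: epr
Title: Enzyme Profile Relatedness from Binary CAZyme Secretome Observations
Version: 1.0.0
Authors@R:
    person("EPR", "Maintainers", email = "epr@example.org", role = c("aut", "cre"))
Description: Builds binary "Function;Family" observation matrices from
    per-protein CAZyme annotations and secretion-tool predictions, scores
    genome-to-genome enzyme profile relatedness with the Yule dissimilarity,
    and derives dendrograms, flat clusters, low-stress multidimensional
    scaling maps and section-level profiling statistics (shared and absent
    observations, present:absent ratio, enzyme-producer types I-III).
    Includes a seeded hierarchical synthetic-data generator so the whole
    pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
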