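Package: pbsi
Title: Partition-Based Selection of Influential Spreaders in Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies multiple influential and well-scattered spreaders in
    complex networks by combining a gravity k-shell centrality with a
    community-proportional seed allocation. Includes the classical benchmark
    rankers (degree, closeness, betweenness, VoteRank, HybridRank, indirect
    spreading strength, entropy-based improved k-shell, true spreading
    ability), a discrete-time SIR contact-process simulator for evaluating
    seed sets, scatter and profit metrics, synthetic network generators with
    planted community structure, and tidy experiment harnesses with ggplot2
    helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
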