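Package: lctree
Title: Latent Class Trees for Categorical and Top-2 Ranking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Divisive hierarchical latent class analysis for categorical
    response data. Latent class models are estimated by weighted maximum
    likelihood (EM), classes are split recursively with proportional
    (posterior-weight) assignment, and each split is gated by an
    information criterion. A relative-improvement-of-fit measure sizes the
    first (root) split, allowing nonbinary root splits. Includes a latent
    class discrete-choice model for items where respondents rank a first
    and second choice among alternatives, synthetic-data generators for
    benchmark class configurations, a simulation-study runner for the
    relative-improvement measure, and tree export to JSON and Graphviz DOT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
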