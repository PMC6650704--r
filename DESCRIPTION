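Package: packdom
Title: Dominance Hierarchies and Agonistic-Interaction Networks in Social Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing dominance hierarchies from agonistic
    interaction data in social animal groups. Builds directed and
    undirected, binary and count-weighted interaction networks from
    event-level logs; infers ordinal dominance ranks from submissive
    interactions by inconsistency minimisation (I&SI) initialised with
    David's scores; specifies, evaluates and fits exponential random
    graph models (ERGMs) for binary and count-valued networks by maximum
    pseudolikelihood and Monte-Carlo maximum likelihood; simulates
    network ensembles from fitted models; and computes a rank-resolved,
    simulation-based goodness-of-fit surface that localises hierarchy
    instability by hierarchy position and rank distance. Includes a
    synthetic pack generator with a sex-age-graded latent hierarchy for
    testing and parameter-recovery experiments, and an end-to-end
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
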