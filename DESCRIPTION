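Package: malnet
Title: Knowledge-Graph and Scale-Free Network Analysis of Medical Malpractice Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates a typed knowledge graph of medical
    malpractice litigation cases (patients, hospitals, specialties,
    diseases, comorbidities, errors, outcomes, claims), generates
    schema-conforming synthetic networks with tunable preferential
    attachment, and decides whether a degree distribution is scale-free:
    maximum-likelihood power-law fitting with Kolmogorov-Smirnov selection
    of the lower cutoff, semi-parametric bootstrap goodness-of-fit,
    exponential and log-normal alternatives with Vuong-style
    likelihood-ratio comparison, and hub identification via degree,
    closeness, betweenness and PageRank centrality under the directed,
    unnormalized conventions used in malpractice network studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
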