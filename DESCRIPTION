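Package: herdnet
Title: Network Analysis of Regional Livestock Trade
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds yearly and overall directed, weighted market networks
    from livestock movement records and characterises them the way
    veterinary epidemiologists study regional trade: preprocessing of raw
    survey entries (splitting origin-survey-destination triplets,
    excluding self-loops, incomplete and unmapped entries), descriptive
    summaries, network- and node-level statistics, a spatial propinquity
    test on Haversine distances, degree-preserving configuration-model
    null ensembles with z-scores, heavy-tailed degree-distribution model
    selection (discrete power law and log-normal with lower-cutoff
    selection, bootstrap goodness of fit and a Vuong comparison),
    fast-greedy modularity communities and key-market identification.
    A seeded synthetic-data generator emulates the survey data so the
    whole pipeline is testable without access to the original records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
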