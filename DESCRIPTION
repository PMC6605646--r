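Package: spiderling
Title: Agent-Based Simulation and Survival Analysis of Spiderling
    Aggregation and Dispersal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the onset of natal dispersal in gregarious
    spiderlings of solitary spiders. Implements a heavy-tailed stop/aggregate
    survival model with a power-law-with-cutoff leaving hazard, group-size
    scaling of the leaving parameter and a maturational (ontogenic) shift in
    mobility; a stochastic agent-based simulator of stop-and-go movement in a
    partitioned circular arena with wall-following, diffusive central movement
    and interattraction; trajectory-superimposition (virtual pair) null models
    with Cox proportional-hazards quantification of interattraction; and
    wall-aware spatial dispersal metrics (geodesic nearest-neighbour
    distances, activity indices, minimal-displacement identity assignment,
    onset-of-mobility detection). A synthetic-data generator emulates every
    input the analysis consumes, so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
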