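Package: oxaging
Title: Integrated Oxidative-Aging Marker Screening for Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline linking aging, oxidative stress and
    type 2 diabetes mellitus at the systems level: ReliefF feature ranking
    with correlation-distance k-nearest-neighbour prediction of aging and
    disease markers, a mediation-style screen that assembles
    aging-oxidative-disease gene triples from differential-coexpression
    statistics with permutation, confounder and pleiotropy filters,
    Metropolis-Hastings sensitivity analysis of the retained triples,
    differential-coexpression network construction with shortest-path
    betweenness markers, hypergeometric gene-set enrichment, and a
    pan-cancer differential-expression and survival stage. A synthetic
    cohort generator with planted ground truth makes every stage testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
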