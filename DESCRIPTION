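Package: klbn
Title: Exact Kullback-Leibler Divergence Between Discrete Bayesian Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the exact Kullback-Leibler divergence between the joint
    distributions of two discrete Bayesian networks defined on the same
    variables, using the decomposition of the expected log-likelihood into
    family marginals. Three engines are provided: brute-force joint
    enumeration, per-parent-configuration evidence propagation, and a cached
    variable-elimination engine that plans all family-marginal queries
    symbolically, reuses repeated factor operations through an operation
    repository, and reclaims memory with time-stamped potential deletion.
    Includes discrete potential algebra, relevance pruning (ancestral sets
    and Bayes-ball), a min-weight elimination-ordering heuristic, BIF and
    JSON network input/output, forward sampling, and a synthetic generator
    of random network pairs.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
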