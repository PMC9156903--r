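Package: rescuedip
Title: Survival of Populations Facing an Abrupt Environmental Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Closed-form survival probabilities for a haploid population hit
    by an instantaneous environmental change, combining branching-process
    evolutionary-rescue theory with Wright's stationary distribution of a
    mildly deleterious survival allele under drift, selection and symmetric
    mutation. Provides the confluent-hypergeometric closed form for the
    marginal survival probability, its quadrature oracle, the decomposition
    into standing-variation and de-novo components, a numerical finder for
    the vulnerable intermediate population size at which survival is locally
    minimized, and stochastic validation simulators (independent-lineage
    branching process and a Ricker density-regulated variant) initialized
    from the discretized stationary distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
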