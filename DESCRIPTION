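Package: gsfutility
Title: Optimal Futility Stopping Boundaries for Two-Stage Group
    Sequential Designs with a Continuous Endpoint
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytic derivation of "optimal" non-binding futility
    stopping boundaries for two-stage group sequential superiority
    trials comparing a continuous endpoint between two groups with the
    inverse normal combination test and Pocock local significance
    levels.  A futility boundary is admissible when the probability of
    wrongly stopping for futility under the relevant standardized
    effect is bounded and the induced global power loss is bounded; the
    optimal boundary is the smallest admissible one, which maximizes
    the probability of correctly stopping under null or non-relevant
    effects.  Includes full operating-characteristic reporting,
    sensitivity grids over the admissible parameters, a Monte-Carlo
    oracle at the test-statistic and patient level, and a command-line
    reporting tool.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    mvtnorm,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
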