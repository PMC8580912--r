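Package: indexgain
Title: Optimum Allocation and Expected Selection Gain for Two-Trait Index
    Selection in Hybrid Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic model calculations of expected selection gain when
    two traits are improved simultaneously in hybrid breeding programs that
    combine genomic and phenotypic selection. Builds Smith-Hazel, base and
    restricted (Kempthorne-Nordskog) selection indices from testcross variance
    components, propagates them through multistage truncation selection using
    Tallis-type first moments of the truncated multivariate normal
    distribution, supports independent culling levels as a benchmark, and
    finds the budget-constrained optimum allocation of initial doubled-haploid
    lines, test locations and testers by exhaustive grid search. Gains are
    annualized by breeding-cycle length so that strategies of different speed
    can be compared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mvtnorm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
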