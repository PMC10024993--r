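Package: invaderkit
Title: Invasion Fitness and Evolutionarily Stable Strategies in Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evolutionarily stable strategy (ESS) analysis built on a
    single primitive, the invasion fitness of a rare mutant lineage. Includes
    two-strategy matrix games with mixed strategies and singular-point
    classification; haploid and diploid single-locus selection recursions and
    their correspondence with ESSs; two-locus selection-recombination dynamics
    with external-stability eigenvalue analysis; a mutation-rate-modifier model
    in a cyclically fluctuating environment with pairwise invasibility plots and
    evolutionarily stable mutation rates; and group-structured (island model)
    invasion fitness with inclusive-fitness and group-selection partitions,
    plus the classic sex-ratio application.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
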