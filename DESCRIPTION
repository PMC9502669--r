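Package: kexmatch
Title: Kidney Exchange Matching with a Simulated Secret-Sharing Backend
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores donor-recipient compatibility in kidney exchange programmes
    from six medical criteria (HLA crossmatch, HLA mismatches, ABO blood group,
    age, sex, weight), builds the weighted compatibility digraph over
    incompatible donor-recipient pairs, enumerates exchange cycles of bounded
    length via adjacency-matrix powers, and greedily selects a vertex-disjoint
    set of cycles maximising total transplant-success weight. The whole
    pipeline runs either in cleartext or on a simulated semi-honest two-party
    secret-sharing backend (additive arithmetic and Boolean shares, Beaver
    multiplication triples, share conversions) with closed-form and counted
    circuit-cost accounting. Includes a seeded synthetic cohort generator,
    JSON/CSV input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
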