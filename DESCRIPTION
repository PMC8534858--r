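Package: PhenoMiner
Title: Transparent Machine-Learning Phenotyping from Coded Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A transparent, rule-generating framework for identifying patients
    with a condition of interest from long-format coded electronic health
    records (e.g. Read or SNOMED-CT codes). Patients are represented as
    bag-of-words count vectors over clinical codes; codes are ranked by five
    association indices (chi-squared, Gini gain, information gain, DKM gain,
    and an exact binomial enrichment score); a parsimonious feature subset is
    chosen by rank-ordered forward selection against a validation split; and
    cost-sensitive, rule-exporting decision trees (CART-like, C5.0-like and
    conditional-inference-like profiles) are tuned by stratified
    cross-validated grid search. A synthetic-cohort simulator with planted
    informative codes makes every stage testable without access-restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
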