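Package: fdminer
Title: Discovery of Functional Dependencies, Equivalences and Candidate Keys
    in Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines all minimal functional dependencies, equivalent attribute
    sets and candidate keys from a delimited tabular dataset. The search is a
    level-wise traversal of the power-set lattice of attribute combinations
    in the style of FD_Mine, validating candidate dependencies by partition
    cardinality and pruning the lattice with equivalence, redundancy, closure
    propagation and key rules; candidate generation uses the strict
    all-subsets (apriori) rule so that only minimal dependencies are ever
    checked. Candidate keys are inferred from the discovered dependency set
    with an Armstrong-closure engine and minimum coverage reduction. Includes
    a command-line front end that writes a plain-text report, brute-force
    oracles for desk-scale verification, and a seeded generator of synthetic
    relations with planted dependencies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    optparse,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
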