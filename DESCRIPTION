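Package: ichdprime
Title: Prime-Number Encoding and Arithmetic Diagnosis of ICHD-3 Headache Criteria
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Formalizes the diagnostic criteria of 21 primary headache disorders
    from the International Classification of Headache Disorders, 3rd edition
    (ICHD-3) as propositional formulas over clinical characteristics, assigns
    each characteristic a unique prime number, and encodes every conjunct of a
    criteria set's disjunctive normal form as the product of its primes. A
    patient profile, encoded the same way, satisfies a diagnosis exactly when
    its integer is divisible by at least one criteria encoding, which turns
    diagnosis into exact integer arithmetic. On top of this rule the package
    checks profiles against a curated table of mutually exclusive
    characteristics, exhaustively enumerates all logically consistent dual
    diagnoses by divisibility filtering of pairwise encoding products, and
    classifies the resulting diagnosis pairs by subset and shared-characteristic
    relationships. Exact arbitrary-precision integer arithmetic is implemented
    in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
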