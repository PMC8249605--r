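Package: dvimatch
Title: Joint DNA-Based Disaster Victim Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA-based disaster victim identification (DVI).
    Victim profiles are matched against reference families with missing
    persons by exact pedigree likelihoods (Elston-Stewart peeling over
    nuclear families, with optional proportional mutation modelling).
    The package enumerates and counts all sex-consistent victim to
    missing-person assignments, ranks them by joint likelihood, provides
    sequential (pairwise) search strategies and a combined
    undisputed-plus-joint search, and reports posterior pairing and
    non-pairing probabilities under flat or user-supplied priors.
    Includes gene-drop simulation for power (true positive rate)
    experiments, plain-text input/output for pedigrees, genotypes and
    allele frequency databases, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
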