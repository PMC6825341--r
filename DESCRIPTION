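Package: contactfold
Title: Contact-Guided Ab Initio Protein Folding and Confidence Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for contact-map-guided coarse-grained protein structure
    assembly and model confidence estimation. Computes effective sequence
    counts (Nf) and metagenome contribution fractions (Nff) from multiple
    sequence alignments, builds consensus residue-residue contact sets from
    ranked predictor outputs, evaluates a sigmoidal contact-restraint
    potential, folds chains by replica-exchange Monte Carlo fragment
    assembly, clusters decoy ensembles, and calibrates a C-score confidence
    estimate to an expected TM-score. Ships a synthetic fixture generator
    (toy folds, corrupted contact lists, depth-controlled alignments) so the
    whole pipeline is exercisable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
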