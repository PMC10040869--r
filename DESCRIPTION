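Package: ligandvs
Title: Target-Driven Ligand-Based Virtual Screening with Machine Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular ligand-based virtual screening pipeline for early-stage
    hit identification. Starting from a protein target, the pipeline expands to
    sequence-similar targets via a pluggable homology-search backend, curates
    and labels bioactivity records at configurable potency cutoffs, computes
    molecular fingerprints (Morgan, atom pair, topological torsion, MACCS),
    trains balanced random-forest and multilayer-perceptron classifiers with
    grid search and cross-validation, scores screening libraries, aggregates
    per-model rankings into an ensemble hit list, and profiles hits for
    drug-likeness (QED and physicochemical descriptors). Includes a
    retrospective hold-out validation protocol and a synthetic
    structure-activity fixture generator so the entire pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    ggplot2,
    jsonlite,
    pROC,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel on PATH)
Config/testthat/edition: 3
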