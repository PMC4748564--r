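Package: potencyscreen
Title: Hybrid Similarity and Max-Margin Screening of Anticancer Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ligand-based virtual screening of anticancer molecules from
    binary molecular fingerprints. Ranks individual fingerprints by their
    standalone Matthews correlation coefficient (MCC) and selects those
    above a cutoff, scores query molecules by a dual Tanimoto "potency
    score" (best similarity to any active reference minus best similarity
    to any inactive reference, computed over both present and absent
    bits), trains a radial-basis-function support vector machine on the
    selected bits, and averages the two normalized scores into a hybrid
    classifier. Includes stratified repeated five-fold cross-validation
    with sensitivity, specificity, accuracy, MCC, false-positive rate and
    AUC reporting, SMARTS-based functional-group profiling, native MACCS
    and substructure-key fingerprint computation from SMILES via Open
    Babel, and a synthetic labeled-fingerprint generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
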