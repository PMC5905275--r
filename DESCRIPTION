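Package: tasteRF
Title: Fingerprint-Based Random-Forest Classification of Sweet and Bitter
    Small Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A quantitative structure-taste workflow for small molecules:
    reading and standardizing chemical structures (SMILES, SDF, CSV), duplicate
    removal by InChIKey, four hashed binary substructure fingerprints (Morgan
    circular, pharmacophoric-invariant Morgan, atom-pair and topological
    torsion), Random-Forest classification of sweet versus bitter taste with
    out-of-sample validation (leave-one-out or k-fold), a full evaluation
    panel (accuracy, sensitivity, specificity, precision, F-measure,
    non-error rate, Cohen's kappa, ROC-AUC), class-conditional Bayesian
    feature-discrimination analysis with substructure back-mapping, Tanimoto
    applicability-domain assessment, and confidence-thresholded batch
    screening of compound libraries. Includes a seeded synthetic-molecule
    generator with class-enriched substructure motifs for end-to-end testing
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    ranger,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
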