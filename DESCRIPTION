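Package: brpairscan
Title: Bromine-Isotope-Labeling Metabolomics: Isotopologue Pair Screening,
    QSRR Retention Prediction and Hierarchical Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens centroided LC-MS feature tables for hydroxyl and amino
    compounds derivatized with 5-bromonicotinoyl chloride (BrNC) via the
    natural 79Br/81Br isotopologue pair signature (delta m/z = 1.998 Da,
    intensity ratio about 0.97), classifies derivative type from diagnostic
    MS2 fragment ions, predicts derivative retention times with a
    quantitative structure-retention relationship (QSRR) random-forest
    model, annotates candidates at five confidence levels against compound
    databases, and compares compound profiles across sample groups
    (presence/absence intersections, Welch t-tests with BH correction, and
    PLS-DA variable importance). Includes a synthetic-data generator with a
    planted ground-truth registry for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    randomForest,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    mzR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
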