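Package: lipidForest
Title: Lipid Category and Class Prediction from Elemental Molecular Formulas
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts lipid category and lipid class from non-adducted
    elemental molecular formulas, such as those produced by untargeted
    FT-MS formula-assignment tools. Formulas are converted into
    chemically descriptive feature vectors (CHONPS atom counts, theoretical
    monoisotopic mass and its fractional digits, and the hydrogen deficit
    due to unsaturation) and classified by hierarchical one-vs-rest Random
    Forest models in which per-class models are gated by their parent
    category model. Includes construction of de-duplicated multi-label
    training sets from LMSD-, LMISSD- and HMDB-style exports, convex-hull
    enumeration of CHONPS formula space for generalization testing,
    cross-sample assignment-correspondence filtering at an E-value cutoff,
    and a synthetic-data generator providing labeled formulas and
    multi-sample assignment tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
biocViews: Lipidomics, Metabolomics, MassSpectrometry, Classification,
    Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
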