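Package: oemsol
Title: Thermodynamic-Cycle and Symbolic-Regression Modeling of Organic
    Electrode Material Solubility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for predicting the solubility of redox-active organic
    molecules (organic electrode materials) in nonaqueous electrolytes.
    Implements the thermodynamic cycle of dissolution (solvation plus
    sublimation energetics), voltammetric calibration analysis for
    saturation-solubility determination from cyclic-voltammetry peak
    currents, a native catalogue of topological molecular descriptors
    computed from SMILES, and a sparse symbolic-regression engine
    (mutual-information screening, operator expansion, sure independence
    screening and exhaustive l0-regularized subset regression) that learns
    compact closed-form solubility models from thermodynamic and
    topological descriptors. Includes fixed-structure and full-rerun
    cross-validation protocols, a bagged-tree baseline comparison, and a
    synthetic-data generator emulating the statistical structure of small
    curated solubility data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    randomForest,
    ChemmineR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
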