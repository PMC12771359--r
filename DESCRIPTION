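Package: gagsurr
Title: Machine-Learning Surrogates for MM-GBSA Energies of Protein-Glycosaminoglycan Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns structures of protein-glycosaminoglycan (GAG) complexes into a
    fixed vector of structural and energetic descriptors (local charge and
    polarity counts, geometry, contacts, hydrogen bonds, Shrake-Rupley
    solvent-accessible surface areas, pairwise linear interaction energies) and
    benchmarks eight regression families (elastic net, linear regression,
    linear and RBF-feature support-vector regression, gradient-boosted trees,
    histogram gradient boosting, random forest, and a fully connected neural
    network) as fast surrogates for MM-GBSA binding free energies. Includes
    trajectory input from multi-model PDB files with a per-atom parameter
    sidecar, feature-table utilities (scaling, splitting, group holdout,
    subsampling), uncertainty estimation by Monte Carlo dropout and repeated
    cross-validation, feature-importance analysis by four mechanisms, ablation
    and data-reduction experiments, and synthetic-data generators with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    xgboost,
    ranger,
    e1071,
    MASS,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
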