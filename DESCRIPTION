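Package: shapestage
Title: Subcortical Shape Staging: Radial-Distance Morphometry, Vertex-Wise
    Mixed Models, Spin Tests, and Structured-Sparsity Stage Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for vertex-wise subcortical shape analysis of ordinal
    disease staging. Builds registered spherical-topology surface meshes for
    fourteen bilateral subcortical structures, computes the radial-distance
    ("thickness") shape feature from a medial curve fitted through each
    structure, fits mass-univariate linear mixed-effects models with a
    cohort random intercept and searchlight false discovery rate control,
    assesses spatial similarity of effect maps with a quaternion spin
    permutation test, and trains TV-L1 structured-sparsity logistic and
    cumulative-logit (ordinal) classifiers of disease stage with nested
    cross-validation. A synthetic cohort generator emulates the statistical
    structure of multi-cohort Parkinson's disease shape data for validation
    and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS
Config/testthat/edition: 3
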