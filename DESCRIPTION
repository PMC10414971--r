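Package: gradplast
Title: Longitudinal Analysis of Cortical Gradient and Depth-Varying
    Microstructure Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying training-induced plasticity of cortical
    functional organization and intracortical microstructure. Implements
    diffusion-map embedding of functional connectomes (row-wise proportional
    thresholding, normalized-angle affinity, Procrustes alignment to a
    reference embedding) and the gradient eccentricity statistic; construction
    of equivolumetric intracortical surfaces and parcel-wise quantitative T1
    depth profiles with compartment summaries; massively univariate linear
    mixed-effects contrasts of longitudinal change maps with FDR control;
    spin permutation tests for spatial correspondence that respect spatial
    autocorrelation; and leakage-controlled behavioral prediction with
    sequential feature selection and cross-validated lasso regression. A
    synthetic-data module generates latent-manifold connectomes, crossover
    training cohorts with planted effects, analytic cortical meshes and qT1
    fields, so every stage is testable end-to-end with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    glmnet
Suggests:
    lme4,
    Matrix,
    RNifti,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
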