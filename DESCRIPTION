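Package: cbmr
Title: Coordinate-Based Meta-Regression for Neuroimaging Foci Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-regression of coordinate-based meta-analysis (CBMA) data:
    peak-activation coordinates (foci) pooled across neuroimaging studies are
    modelled with a log-linear spatial intensity parameterized by a pruned,
    renormalized tensor product of cubic B-splines, optionally with study-level
    covariates. Four stochastic models for voxelwise foci counts are provided
    (Poisson, Negative Binomial with a moment-matched convolution, Clustered
    Negative Binomial with a study-level latent effect, and Quasi-Poisson),
    all fitted through a sufficient-statistic factorization that avoids ever
    materializing the study-by-voxel data matrix. Inference includes voxelwise
    Wald tests of spatial homogeneity with delta-method standard errors,
    p-value truncation with Benjamini-Hochberg false discovery rate control,
    general linear hypothesis tests on covariate effects, likelihood-ratio and
    AIC model comparison, goodness-of-fit bias metrics, and a Monte-Carlo
    simulation harness for null calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    RNifti,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    withr,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
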