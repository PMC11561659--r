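Package: sandir
Title: Soma and Neurite Density Imaging for Cortical Microstructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and machine-learned inversion of the SANDI
    (Soma And Neurite Density Imaging) three-compartment model of
    direction-averaged multi-shell diffusion MRI signals in gray matter.
    Includes the Gaussian-phase-distribution restricted-sphere signal with a
    Monte-Carlo random-walk validation oracle, Rician noise synthesis and
    noise-propagation experiments, random-forest parameter estimation, DTI
    and DKI scalar metrics from shell subsets, partial-volume region
    aggregation, the cohort statistics used in lifespan microstructure
    studies (partial Pearson correlation with covariates, Benjamini-Hochberg
    FDR, ANCOVA with post hoc t tests, Fisher r-to-z comparison, linear and
    quadratic age trends), and a synthetic-cohort generator that emulates a
    72-subject lifespan study end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    ranger,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
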