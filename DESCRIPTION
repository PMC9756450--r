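Package: twinace
Title: Biometrical Twin Modelling of Plasma Neurofilament Light and Renal Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Full-information maximum likelihood (FIML) tools for classical twin
    studies of biomarkers, built around the question of how much of the association
    between plasma neurofilament light chain (NfL) and renal function (serum
    creatinine) reflects shared genetic versus unique environmental influences.
    Provides univariate ACE/AE/CE/E and bivariate correlated-factors model fitting
    on monozygotic/dizygotic twin pairs with singletons and arbitrary missingness,
    saturated-model mean and variance homogeneity testing, likelihood-ratio and AIC
    model selection, profile-likelihood confidence intervals, missing-data
    maximum-likelihood correlations with covariate adjustment, a preprocessing
    pipeline (eGFR filtering, covariate residualization, shift-log transform,
    one-sided IQR outlier exclusion), and seeded generators for twin cohorts and
    biomarker panels with known latent structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
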