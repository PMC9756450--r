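# twinace

Biometrical twin modelling of plasma neurofilament light chain (NfL) and
renal function, by full-information maximum likelihood (FIML).

## The problem

Plasma NfL is a blood biomarker of neuroaxonal damage, but its level also
tracks renal function: people who clear the protein less efficiently (higher
serum creatinine, lower eGFR) show higher plasma NfL for the same degree of
neurodegeneration. Two questions follow for anyone using plasma NfL in
research or the clinic:

1. **Does renal function distort plasma NfL as a neurodegeneration marker?**
   If it did, statistically adjusting plasma NfL for creatinine should change
   its correlations with CSF NfL and with brain volumes. `twinace` implements
   the full adjustment pipeline — eGFR filtering, covariate residualization,
   log transform, one-sided 3×IQR outlier exclusion, and missing-data ML
   correlations with and without creatinine adjustment.
2. **Why are plasma NfL and creatinine correlated at all?** With
   monozygotic (MZ) and dizygotic (DZ) twins the phenotypic covariance can be
   decomposed into additive-genetic (A), shared-environment (C) and
   unique-environment (E) sources. `twinace` fits univariate ACE/AE/CE/E
   models and the bivariate **correlated factors** model by raw-data FIML,
   with saturated-model homogeneity testing, AIC/likelihood-ratio model
   selection and profile-likelihood confidence intervals.

## The model

For one trait measured on a twin pair, the implied covariance is

```
Var      = A + C + E
Cov(MZ)  = A + C          (additive-genetic cross-twin correlation 1.0)
Cov(DZ)  = 0.5 A + C      (0.5 for DZ; shared environment correlates 1.0)
```

The bivariate correlated-factors model gives each trait its own A/C/E
factors and links the traits through factor correlations `rg`, `rc`, `re`:

```
within-person cross-trait     rg*sqrt(A1*A2) + rc*sqrt(C1*C2) + re*sqrt(E1*E2)
cross-twin cross-trait (MZ)   rg*sqrt(A1*A2) + rc*sqrt(C1*C2)
cross-twin cross-trait (DZ)   0.5*rg*sqrt(A1*A2) + rc*sqrt(C1*C2)
```

The implied phenotypic correlation reassembles as
`r = sqrt(a²₁a²₂)·rg + sqrt(c²₁c²₂)·rc + sqrt(e²₁e²₂)·re`, where `a²` etc.
are standardized variance shares (`h² = a²`). Every model is estimated on
the raw data: each family contributes the multivariate-normal density of
whatever it has observed, so incomplete pairs and unpaired singletons stay
in the analysis.

## Worked example

Simulate a VETSA-like cohort (218 MZ pairs, 151 DZ pairs, 231 singletons;
plasma NfL and serum creatinine with h² = 0.54 and 0.60, genetic correlation
0.46, unique-environment correlation 0.27, plus covariate effects,
missingness and an eGFR column) and run the complete twin study:

```r
library(twinace)
coh <- simulate_twin_cohort(seed = 2026)
res <- run_study2(coh)

res$twin_correlations
#>        trait zygosity n_pairs    r   lo   hi       p
#>          nfl       MZ     218 0.52 0.41 0.61 5.5e-15
#>          nfl       DZ     151 0.36 0.21 0.49 5.0e-06
#>   creatinine       MZ     203 0.59 0.49 0.67 8.2e-20
#>   creatinine       DZ     138 0.37 0.21 0.50 1.5e-05

res$bivariate$table
#>     model ep    m2ll   df    d_m2ll d_df           p     AIC
#> ACE   ACE 11 701.841 1894        NA   NA          NA 723.841
#> AE     AE  8 704.279 1897   2.43849    3 4.87e-01   720.279
#> CE     CE  8 714.309 1897  12.46816    3 5.94e-03   730.309
#> E       E  5 877.161 1900 175.31972    6 3.34e-35   887.161

res$best$model        # "AE"
round(res$best$shares, 2)
#>     nfl creatinine
#> a2 0.54        0.6
#> c2 0.00        0.0
#> e2 0.46        0.4
```

Reading the output: the MZ pair correlations are roughly double the DZ ones
(a genetic signature), dropping C costs almost no likelihood while dropping A
costs a lot, so the AE model wins on AIC; its standardized components say
about half of the variance in each biomarker is additive-genetic. The best
model's factor correlations (`res$best$rg`, `res$best$re`) and the implied
phenotypic correlation (`res$best$implied_r`) quantify how much of the
NfL–creatinine association is genetic versus environmental. For the
single-trait interface use `twin_ace(pairs, "nfl", model = "AE")`, which
returns a classed fit with `print`, `summary`, `coef`, `logLik`, `AIC`,
`confint` (profile likelihood), `anova` (likelihood-ratio test) and
`simulate` (parametric bootstrap) methods.

The companion panel study (`run_study1`) runs the adjustment sensitivity
analysis on an ADNI-like biomarker panel from `simulate_biomarker_panel()`,
reporting plasma NfL's correlations with CSF NfL and brain volumes before
and after creatinine adjustment, overall and by sex.

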