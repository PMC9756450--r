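---
title: "Methods: FIML twin biometrics for plasma NfL and renal function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FIML twin biometrics for plasma NfL and renal function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the models and their assumptions, the tunable parameters and defaults, what
the synthetic-data generators do and do not emulate, the numerical choices,
and the design decisions taken where more than one defensible option
existed.

## The likelihood

Everything in `twinace` rests on one objective: the raw-data
(full-information) maximum-likelihood function for multivariate normal
data with arbitrary per-row missingness. A row contributes
$-2\log \phi(x_{obs};\mu_{obs},\Sigma_{obs})$, the normal density of its
observed sub-vector under the marginal of the model-implied mean and
covariance; rows with nothing observed contribute zero. This handles
incomplete twin pairs, unpaired singletons (which contribute univariate
marginal terms and are retained throughout, matching a design with several
hundred unpaired participants), and biomarker-specific missingness without
imputation. The implementation (`mvn_m2ll()`) groups rows by missingness
pattern and evaluates the objective from pattern-level sufficient
statistics (count, mean, scatter), so re-evaluation inside an optimizer
costs almost nothing for data with few distinct patterns — complete
twin-pair data reduce to one pattern per zygosity. The pattern-grouped
value is tested to $10^{-10}$ against an independent brute-force per-row
density oracle.

The FIML treatment is valid under ignorable (MCAR/MAR) missingness. The
generators default to MCAR; an MAR mechanism can be emulated by
constructing missingness from generated covariates, but nothing in the
package assumes it.

## Twin models

For one trait, the ACE model implies per-pair covariance
$\mathrm{Var} = A + C + E$, cross-twin covariance $A + C$ (MZ) or
$0.5A + C$ (DZ): the additive-genetic cross-twin correlation is fixed at
1.0 / 0.5 by biology, the shared environment correlates 1.0 in both
zygosities, and E is uncorrelated within pairs (it includes measurement
error). The model further assumes no gene–environment interaction or
correlation, non-random mating, and mean/variance homogeneity across twin
order and zygosity; the last assumption is testable (below), the others
are structural. Sub-models AE, CE, E fix the dropped components to zero.

The bivariate **correlated factors** model gives each trait its own A/C/E
and couples the traits through factor correlations $r_g, r_c, r_e$; the
cross-twin cross-trait covariance carries $r_g\sqrt{A_1A_2}$ (halved for
DZ) plus $r_c\sqrt{C_1C_2}$ and never $r_e$. No Cholesky or more-than-two-
trait variants are provided. The implied phenotypic correlation is
$\sqrt{a^2_1a^2_2}\,r_g + \sqrt{c^2_1c^2_2}\,r_c + \sqrt{e^2_1e^2_2}\,r_e$,
and a property test checks that it agrees with the directly estimated
cross-trait correlation on the same data to 0.01.

**Parameterization.** Paths $a, c, e$ are optimized unconstrained and
variances reported as squares (non-negativity by construction); factor
correlations go through $\tanh$ (bounds by construction). Path sign
indeterminacy is immaterial because only squares are reported, and
correlation signs are identified because cross-trait covariances use
$r\sqrt{A_1A_2}$ with the non-negative root. The means model inside
ACE-family fits is a single grand mean per trait — justified by running
the homogeneity sequence first, and matching the convention that produces
the published parameter counts (univariate ACE/AE/CE/E: 4/3/3/2;
bivariate: 11/8/8/5).

**Optimization.** BFGS with numerical gradients, relative function
tolerance $10^{-12}$, five deterministic multi-starts jittered around
moment-based initial values (Falconer: $a^2_0 = 2(r_{MZ}-r_{DZ})$,
$c^2_0 = 2r_{DZ}-r_{MZ}$, floored at 0.01), with a Nelder-Mead fallback
if BFGS stalls on the admissibility penalty. Covariances that fail a
Cholesky factorization inside optimization return a large penalty
($10^{10}$); outside optimization they are hard errors. Nested-likelihood
monotonicity is enforced: if a sub-model ever beats the model it is nested
in (an optimizer artifact on flat surfaces), the fuller model is refitted
from the sub-model's solution, with dropped-component paths re-seeded just
off zero (a path at exactly zero is a stationary point of the squared
parameterization and would pin the refit).

**Homogeneity testing.** The saturated model frees all 10 univariate
moments (per-zygosity, per-twin-order means and variances plus
per-zygosity cross-twin covariances); the cumulative constraint ladder
equates means within zygosity (ep 8), means across zygosity (7), variances
within (5) and across (4) zygosity, giving likelihood-ratio tests with
df 2/3/5/6 against the saturated model. The verdict threshold defaults to
$p = 0.01$, i.e. a nominal 0.05 Bonferroni-corrected across the
comparisons. Null calibration is part of the acceptance suite: at 200
pairs per zygosity the per-step rejection rates sit inside the binomial
95% band around 5% over 500 replicates.

**Model comparison.** AIC $= -2LL + 2\,ep$, lowest wins, ties broken
toward fewer parameters. Likelihood-ratio p values use the naive
$\chi^2$ reference with no 50:50 boundary mixture — the convention of the
published twin tables this package mirrors. For variance components tested
on their boundary (AE vs ACE) this is conservative; it is documented
rather than "fixed" so that comparison tables reproduce the published
arithmetic. $\chi^2$/RMSEA/CFI are computed against the saturated model
and an independence baseline (means and variances free, all covariances
zero — the baseline is a package choice, no published one being stated);
RMSEA's sample-size unit is the number of families, another choice the
source convention leaves open.

**Profile confidence intervals.** Bounds are where the profile $-2LL$
(re-optimizing all other parameters) rises by $\chi^2_{1,0.95} = 3.841$,
found by root bisection; shares are profiled by fixing
$X_i = \tfrac{s}{1-s}(\text{other components})$ and correlations by fixing
the $\tanh$ parameter. Intervals are clipped at natural bounds (0/1 for
shares, ±1 for correlations) with a `clipped` flag rather than silently
truncated. Fisher-z intervals are available as a cross-check for plain
correlations and agree with the profile in the quadratic (large-$n$)
limit, which the test suite verifies.

## Preprocessing

The pipeline order is fixed and logged: eGFR filter → residualization →
log → one-sided IQR filter.

* **eGFR filter.** Records with eGFR `< 30` mL/min/1.73 m² (stage 4–5
  chronic kidney disease) are excluded; missing eGFR is kept and flagged.
  The threshold is a parameter. eGFR is an input column — the package
  never computes it from creatinine.
* **Residualization.** OLS on intercept + covariates, both twins stacked
  into one regression so coefficients are shared (a `by` argument gives
  per-group fits). Categorical covariates are one-hot encoded with the
  most frequent level as reference. Rows missing a covariate are excluded
  listwise from that variable's regression only. Rank deficiency is an
  error naming the collinear columns. Reported per term: $\beta$, $t$,
  $p$. Sex is deliberately *not* a residualization covariate for the
  biomarkers (the analysis stratifies by sex instead) but *is* one for
  brain volumes in the ADNI-like configuration.
* **Log transform.** "Residualize, then log" cannot apply literally to
  mean-zero residuals. The default adds back the variable's raw sample
  mean before logging (`shift_log_transform()`), erroring — never
  clipping — if any shifted value is non-positive. For strongly
  right-skewed markers (CSF NfL has a coefficient of variation near 0.75)
  that guard will trip on realistic data, so the pipeline wrapper offers
  `order = "log_first"` (log the strictly positive raw values, then
  residualize), which the study runners use. Both orders are monotone
  re-expressions of the same information; correlations of the processed
  scores differ only through the transform choice.
* **IQR filter.** Points strictly above $Q_3 + k\,\mathrm{IQR}$ (default
  $k = 3$) are excluded; one-sided, single pass, quartiles computed once
  on the input by linear interpolation between order statistics
  (`stats::quantile` type 7 — the mainstream default; the method is a
  parameter). A constant vector excludes nothing; a value exactly on the
  threshold is kept. Every exclusion is counted by cause and surfaced in
  the run log; nothing is dropped silently.

## Missing-data correlations and adjustment

`fiml_correlation()` fits the bivariate normal to raw data (5 parameters)
and reports the ML correlation, profile-likelihood CI and the
likelihood-ratio p for $r = 0$; on complete data it equals the
product-moment estimate with $1/n$ scaling. `adjusted_correlation()`
residualizes $x$ on the adjusters first and records them as immutable
provenance in the estimate. `correlation_table()` assembles the full
report — per variable pair, per stratum (full sample / male / female),
with and without adjustment, plus the definitional delta column — and
emits not-estimable rows rather than dropping strata with $n < 4$.
Comparing male and female correlation magnitudes uses a Fisher-z
two-sample test; that test is this package's addition (no test is named
in the source analyses) and is labelled as such in its documentation.

## The generators

`simulate_twin_cohort()` draws, per family, stacked latent
A/C/E factors with the exact Kronecker correlation structure (A cross-twin
1.0/0.5 and cross-trait $r_g$; C shared within family, cross-trait $r_c$;
E independent across twins, cross-trait $r_e$), via eigendecomposition so
the singular MZ additive-genetic block is handled exactly — no rejection
sampling, and sample cross-twin covariance matrices converge to the
closed-form implied matrices (checked at 10,000 pairs). Singletons are
generated as full pairs with one record dropped, preserving the marginal
distribution of observed twins; twin order is randomized afterwards so no
order artifact can leak into constrained fits.

Defaults mirror the VETSA-like study conditions: 218 MZ pairs, 151 DZ
pairs, 231 singletons; plasma NfL 13.18 (SD 6.88) ng/L with $h^2 = 0.54$;
serum creatinine 1.04 (SD 0.21) mg/dL with $h^2 = 0.60$; AE structure with
$r_g = 0.46$, $r_e = 0.27$; covariate slopes set to the reported
regression coefficients (age and BMI for NfL, BMI and ethnicity for
creatinine); creatinine missing at the observed 33/969 rate. Biomarkers
are generated log-normal — the ACE structure, means and slopes live on the
log scale (scale parameters chosen to match the natural-scale means and
SDs), so values are strictly positive and right-skewed like real assay
data and the pipeline's log transform recovers the exact generating
structure. An eGFR column tracks creatinine inversely (correlation
$\approx -0.65$) so the CKD filter has something realistic to act on.
Storage time (months) and the site indicator have no stated scale; their
defaults are realistic choices, not sourced values.

`simulate_biomarker_panel()` builds the ADNI-like panel from two
*orthogonal* standard-normal latents: a neurodegeneration factor (plasma
NfL and CSF NfL load positively, hippocampal/medial-temporal/whole-brain
volumes negatively) and a renal factor loading only on plasma NfL and
creatinine — the constructor rejects any renal loading elsewhere, encoding
the hypothesis that the variance plasma NfL shares with creatinine is
independent of the variance it shares with neurodegeneration markers. A
third body-size latent links volumes to intracranial volume. Loadings
default to values that reproduce the reported correlation magnitudes
(plasma–CSF ≈ 0.53, plasma–creatinine ≈ 0.26, plasma–hippocampus ≈ −0.21);
scales match the reported sample characteristics; sex shifts creatinine
and CSF NfL so that their small marginal association vanishes under sex
control; CSF NfL is missing at the observed 96/393 rate.

Because the two factors are orthogonal, creatinine adjustment changes the
plasma-NfL correlations with CSF NfL and volumes only through sampling
noise — the acceptance suite bounds all such deltas by 0.03 at
$n = 5{,}000$. `inject_outliers()` places contamination a configurable
number of IQRs above the clean third quartile (warning when the magnitude
cannot clear a 3×IQR filter) and returns the injected indices for
assertion.

What the generators do **not** emulate: assay-level noise processes
(hemolysis, plate or kit effects), longitudinal waves, MAR/MNAR
missingness, sex-limited genetic effects (the twin defaults are an
all-male cohort), or real ADNI/VETSA records — those are access-restricted
and no part of the package reads them. Passing tests therefore demonstrate
correctness of the machinery under the stated latent structure, not
properties of the restricted datasets.

## Numerical conventions and degenerate inputs

* df bookkeeping: `df = (observed data values) − ep` everywhere, the
  convention that reproduces the published df columns on data of known
  dimensions; `AIC = −2LL + 2·ep` exactly.
* A single-zygosity table is refused (A and C are not separately
  identifiable without the MZ/DZ contrast).
* Zero-variance variables are errors in all correlation estimators; a
  fitted component collapsing to the zero boundary is flagged, not
  errored.
* Generator validation: non-negative components, $|r| \le 1$, and a
  defense-in-depth positive-semidefiniteness check of each implied
  zygosity block (unreachable for admissible inputs under the
  correlated-factors construction, which is PSD by construction).
* The cohort's JSON parameter sidecar is written with 17 significant
  digits so the generating model round-trips bit-identically.
* Seeds: every generator takes an explicit integer seed; equal seeds give
  identical output, and the study runners stamp outputs with a config
  hash so reruns can be diffed byte for byte.

## Problem sizes in the test suite

Simulation-based tests choose sizes that make their tolerances meaningful:
closed-form sanity checks at 10,000 pairs (±0.02 on implied pair
correlations), parameter recovery at 2,000 pairs per zygosity × 50
replicates (±0.02 on means of $h^2$, $r_g$, $r_e$ — the headline
acceptance run), a reduced recovery grid (1,000 pairs × 8 replicates,
±0.05) for corner configurations, null calibration of the homogeneity
ladder at 200 pairs per zygosity × 500 replicates, and the adjustment
invariance property at $n = 5{,}000$ panel subjects. These are the
package's own choices of precision targets.

## Known limitations

* The naive-$\chi^2$ boundary issue above: p values for dropping variance
  components are conservative.
* Profile CIs re-optimize nuisance parameters by full refits; for the
  bivariate model at large $n$ they are accurate but not fast.
* The AE/CE/E sub-models fix components at exactly zero rather than
  estimating near-boundary values; boundary flags on the full model are
  the intended diagnostic.
* Only one- and two-trait models are supported; no sex-limitation or
  gene–environment interaction models; no causal mediation between
  creatinine and NfL.
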