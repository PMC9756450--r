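# Twin-cohort and biomarker-panel generators.

test_that("perfect genetic determination makes MZ twins identical", {
  gm <- twin_acemodel(traits = "x", A = c(x = 1), C = c(x = 0),
                      E = c(x = 0), means = c(x = 5),
                      covariates = list(), missing = c(x = 0))
  coh <- simulate_twin_cohort(twin_design(50, 10, 0,
                                          singleton_zygosity_mix = 0.5),
                              gm, seed = 2)
  mz <- coh$pairs[coh$pairs$zygosity == "MZ", ]
  expect_equal(mz$x_1, mz$x_2, tolerance = 1e-12)
})

test_that("pure unique-environment traits leave both zygosities
           uncorrelated", {
  gm <- twin_acemodel_std(h2 = 0)
  coh <- simulate_twin_cohort(twin_design(10000, 10000, 0), gm, seed = 3)
  for (z in c("MZ", "DZ")) {
    d <- coh$pairs[coh$pairs$zygosity == z, ]
    expect_lt(abs(cor(d$trait1_1, d$trait1_2)), 0.05)
  }
})

test_that("standardized A=0.6 C=0.2 gives pair correlations near 0.8 (MZ)
           and 0.5 (DZ) at 10,000 pairs", {
  gm <- twin_acemodel_std(h2 = 0.6, c2 = 0.2)
  coh <- simulate_twin_cohort(twin_design(10000, 10000, 0), gm, seed = 4)
  mz <- coh$pairs[coh$pairs$zygosity == "MZ", ]
  dz <- coh$pairs[coh$pairs$zygosity == "DZ", ]
  expect_equal(cor(mz$trait1_1, mz$trait1_2), 0.8, tolerance = 0.02 / 0.8)
  expect_equal(cor(dz$trait1_1, dz$trait1_2), 0.5, tolerance = 0.02 / 0.5)
})

test_that("sample cross-twin covariance matrices converge to the implied
           matrices within 3 standard errors at 10,000 pairs", {
  gm <- twin_acemodel_std(h2 = c(0.54, 0.60), rg = 0.46, re = 0.27)
  coh <- simulate_twin_cohort(twin_design(10000, 10000, 0), gm, seed = 5)
  cols <- c("trait1_1", "trait2_1", "trait1_2", "trait2_2")
  for (z in c("MZ", "DZ")) {
    y <- as.matrix(coh$pairs[coh$pairs$zygosity == z, cols])
    implied <- ace_expected_cov(c(0.54, 0.60), c(0, 0), c(0.46, 0.40),
                                zygosity = z, rg = 0.46, re = 0.27)
    emp <- cov(y)
    # rough SE of a covariance of unit-variance traits at n = 10,000
    se <- 1.5 / sqrt(nrow(y))
    expect_lt(max(abs(emp - implied)), 3 * se)
  }
})

test_that("the same seed reproduces the cohort exactly and the model echo
           round-trips through the JSON sidecar bit-identically", {
  a <- simulate_twin_cohort(twin_design(30, 30, 10), seed = 9)
  b <- simulate_twin_cohort(twin_design(30, 30, 10), seed = 9)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$subjects, b$subjects)
  paths <- write_cohort(a, tempfile())
  echo <- jsonlite::read_json(paths[["params"]], simplifyVector = TRUE)
  expect_identical(unlist(echo$model$A), unlist(a$model$A))
  expect_identical(echo$model$rg, a$model$rg)
  expect_identical(unlist(echo$model$means), unlist(a$model$means))
  expect_identical(unlist(echo$model$missing), unlist(a$model$missing))
})

test_that("singletons appear as families with exactly one observed twin, in
           the configured number and zygosity mix", {
  coh <- simulate_twin_cohort(twin_design(40, 40, 20,
                                          singleton_zygosity_mix = 0.75),
                              twin_acemodel_std(h2 = 0.5), seed = 6)
  s <- coh$pairs[coh$pairs$singleton, ]
  expect_equal(nrow(s), 20)
  expect_equal(sum(s$zygosity == "MZ"), 15)
  expect_true(all(is.na(s$trait1_2)))
  expect_true(all(!is.na(s$trait1_1)))
  expect_equal(nrow(coh$subjects), 2 * 80 + 20)
})

test_that("missingness lands within the binomial 99% interval of the
           configured rate", {
  gm <- twin_acemodel_std(h2 = 0.5)
  gm$missing["trait1"] <- 0.2
  coh <- simulate_twin_cohort(twin_design(2000, 2000, 0), gm, seed = 7)
  vals <- c(coh$pairs$trait1_1, coh$pairs$trait1_2)
  n <- length(vals)
  ci <- qbinom(c(0.005, 0.995), n, 0.2) / n
  frac <- mean(is.na(vals))
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("invalid generating models are rejected, including post-hoc
           corruption of a constructed model", {
  expect_error(twin_acemodel_std(h2 = 1.2), "non-negative")
  expect_error(twin_acemodel_std(h2 = c(0.5, 0.5), rg = 1.5),
               "exceed 1")
  # the factor-correlation parameterization guarantees positive
  # semidefiniteness for admissible inputs; the validator still catches a
  # corrupted model object before simulation
  gm <- twin_acemodel_std(h2 = c(0.5, 0.5), rg = 0.3)
  gm$rg <- 1.7
  expect_error(simulate_twin_cohort(twin_design(10, 10, 0), gm,
                                    seed = 1),
               "exceed 1")
})

test_that("panel factors are orthogonal by construction: zeroing one factor
           removes exactly its correlations", {
  m0 <- panel_model()
  # no renal factor -> plasma NfL and creatinine uncorrelated
  m <- m0
  m$loadings$plasma_nfl["renal"] <- 0
  m$loadings$creatinine["renal"] <- 0
  m$sex_effect["creatinine"] <- 0
  m$age_slope[c("plasma_nfl", "creatinine")] <- 0
  m$bmi_slope[c("plasma_nfl", "creatinine")] <- 0
  pan <- simulate_biomarker_panel(8000, m, seed = 11)
  expect_lt(abs(cor(log(pan$plasma_nfl), log(pan$creatinine),
                    use = "pair")), 0.05)
  # no neuro factor -> plasma NfL and CSF NfL uncorrelated (the shared
  # age slope is zeroed too: the claim is about the factor structure)
  m <- m0
  m$loadings$plasma_nfl["neuro"] <- 0
  m$loadings$csf_nfl["neuro"] <- 0
  m$age_slope[c("plasma_nfl", "csf_nfl")] <- 0
  m$bmi_slope["plasma_nfl"] <- 0
  pan <- simulate_biomarker_panel(8000, m, seed = 12)
  expect_lt(abs(cor(log(pan$plasma_nfl), log(pan$csf_nfl),
                    use = "pair")), 0.05)
})

test_that("the panel refuses degenerate sizes and a renal loading on a
           neurodegeneration marker", {
  expect_error(simulate_biomarker_panel(2, seed = 1), "n < 3")
  bad <- panel_model()
  expect_error(panel_model(loadings = modifyList(
    bad$loadings, list(csf_nfl = c(neuro = 0.7, renal = 0.3)))),
    "renal factor")
})

test_that("cohort CSV + JSON sidecar round-trip preserves the data", {
  coh <- simulate_twin_cohort(twin_design(10, 10, 5), seed = 13)
  dir <- tempfile()
  paths <- write_cohort(coh, dir)
  back <- read.csv(paths[["pairs"]])
  expect_equal(back$nfl_1, coh$pairs$nfl_1, tolerance = 1e-12)
  meta <- jsonlite::read_json(paths[["params"]], simplifyVector = TRUE)
  expect_equal(meta$seed, 13)
  expect_equal(meta$design$n_mz_pairs, 10)
})
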