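# Saturated models, homogeneity testing, twin correlations, and the
# ACE-family / correlated-factors fits.

test_that("unconstrained saturated MLE equals closed-form sample moments
           on complete data", {
  pairs <- toy_pairs(n_mz = 150, n_dz = 150, h2 = 0.5, seed = 51)
  sat <- twin_saturated(pairs, "trait1")
  for (z in c("MZ", "DZ")) {
    y <- as.matrix(pairs[pairs$zygosity == z,
                         c("trait1_1", "trait1_2")])
    n <- nrow(y)
    expect_equal(sat$moments[[z]]$mu, colMeans(y), tolerance = 1e-4,
                 ignore_attr = TRUE)
    ml_cov <- cov(y) * (n - 1) / n
    expect_equal(sat$moments[[z]]$sigma, ml_cov, tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("parameter counts follow the saturated-constraint ladder
           10/8/7/5/4 with df changes 2/3/5/6", {
  pairs <- toy_pairs(n_mz = 60, n_dz = 60, h2 = 0.5, seed = 52)
  h <- homogeneity_sequence(pairs, "trait1")
  expect_equal(h$table$ep, c(10, 8, 7, 5, 4))
  expect_equal(h$table$d_df[-1], c(2, 3, 5, 6))
  expect_equal(h$table$AIC, h$table$m2ll + 2 * h$table$ep)
  # df bookkeeping: observed data values minus ep
  expect_equal(h$table$df, sum(!is.na(pairs[c("trait1_1",
                                              "trait1_2")])) -
                 h$table$ep)
})

test_that("a large twin-order mean shift is rejected at the mean-within
           step with high power", {
  rej <- sapply(1:20, function(i) {
    pairs <- toy_pairs(n_mz = 100, n_dz = 100, h2 = 0.5, seed = 600 + i)
    pairs$trait1_2 <- pairs$trait1_2 + 0.8  # ~0.8 SD order effect
    h <- homogeneity_sequence(pairs, "trait1")
    h$table$p[h$table$model == "mean_within"] < 0.01
  })
  expect_gte(mean(rej), 0.95)
})

test_that("ML twin correlations recover generating values and respect
           exchangeability", {
  gm <- twin_acemodel_std(h2 = 0.3, c2 = 0.3)  # rMZ 0.6, rDZ 0.45
  coh <- simulate_twin_cohort(twin_design(5000, 5000, 0), gm, seed = 53)
  tc <- twin_correlations(coh$pairs, "trait1")
  expect_equal(tc$r[tc$zygosity == "MZ"], 0.6, tolerance = 0.03 / 0.6)
  expect_equal(tc$r[tc$zygosity == "DZ"], 0.45, tolerance = 0.03 / 0.45)
  expect_true(all(tc$lo <= tc$r & tc$r <= tc$hi))
  # permuting twin order leaves the constrained estimates unchanged
  perm <- permute_twin_order(coh$pairs, "trait1", seed = 99)
  tc2 <- twin_correlations(perm, "trait1")
  expect_equal(tc$r, tc2$r, tolerance = 1e-6)
})

test_that("identical MZ twins give a pair correlation of one", {
  gm <- twin_acemodel(traits = "x", A = c(x = 1), C = c(x = 0),
                      E = c(x = 1e-8), means = c(x = 0),
                      covariates = list(), missing = c(x = 0))
  coh <- simulate_twin_cohort(twin_design(60, 30, 0), gm, seed = 54)
  tc <- twin_correlations(coh$pairs, "x")
  expect_gt(tc$r[tc$zygosity == "MZ"], 0.999)
})

test_that("univariate fits carry the right parameter counts and recover an
           AE structure", {
  pairs <- toy_pairs(n_mz = 2000, n_dz = 2000, h2 = 0.54, seed = 55)
  fam <- twin_ace_models(pairs, "trait1")
  expect_equal(unname(sapply(fam$fits, function(f) f$ep)),
               c(4, 3, 3, 2))
  ae <- fam$fits$AE
  expect_equal(unname(ae$h2), 0.54, tolerance = 0.05 / 0.54)
  expect_equal(sum(ae$shares[, 1]), 1, tolerance = 1e-6)
  expect_equal(ae$AIC, ae$m2ll + 2 * ae$ep)
  expect_equal(ae$df, ae$n_obs - ae$ep)
})

test_that("pure-E data pushes the fitted ACE model to e2 near one", {
  pairs <- toy_pairs(n_mz = 5000, n_dz = 5000, h2 = 0, seed = 56)
  fit <- twin_ace(pairs, "trait1", model = "ACE")
  expect_gte(fit$shares["e2", 1], 0.95)
  expect_true(fit$boundary)
})

test_that("nested-model -2LL monotonicity holds across datasets", {
  for (s in 57:59) {
    pairs <- toy_pairs(n_mz = 200, n_dz = 200,
                       h2 = c(0.3, 0.6), rg = 0.5, re = 0.2, seed = s)
    for (trs in list("trait1", c("trait1", "trait2"))) {
      fam <- twin_ace_models(pairs, trs)
      m <- sapply(fam$fits, function(f) f$m2ll)
      expect_gte(m[["E"]] - m[["CE"]], -1e-4)
      expect_gte(m[["CE"]] - m[["ACE"]], -1e-4)
      expect_gte(m[["AE"]] - m[["ACE"]], -1e-4)
      expect_gte(m[["E"]] - m[["AE"]], -1e-4)
    }
  }
})

test_that("bivariate parameter counts are 11/8/8/5 and the correlated
           factors AE fit recovers rg and re", {
  pairs <- toy_pairs(n_mz = 2000, n_dz = 2000, h2 = c(0.54, 0.60),
                     rg = 0.46, re = 0.27, seed = 60)
  fam <- twin_ace_models(pairs, c("trait1", "trait2"))
  expect_equal(unname(sapply(fam$fits, function(f) f$ep)),
               c(11, 8, 8, 5))
  ae <- fam$fits$AE
  expect_equal(ae$rg, 0.46, tolerance = 0.06 / 0.46)
  expect_equal(ae$re, 0.27, tolerance = 0.06 / 0.27)
  expect_true(is.na(ae$rc))
  # implied phenotypic correlation agrees with the direct ML estimate of
  # the within-person cross-trait correlation
  direct <- fiml_correlation(c(pairs$trait1_1, pairs$trait1_2),
                             c(pairs$trait2_1, pairs$trait2_2))
  expect_equal(ae$implied_r, direct$r, tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("parameter recovery holds across a grid of generating values", {
  grid <- list(list(h2 = 0.2, rg = 0), list(h2 = 0.8, rg = 0.9),
               list(h2 = 0.54, rg = 0.46))
  for (g in grid) {
    est <- sapply(1:8, function(i) {
      pairs <- toy_pairs(n_mz = 1000, n_dz = 1000,
                         h2 = c(g$h2, 0.6), rg = g$rg, re = 0.2,
                         seed = 700 + 10 * g$h2 * 10 + i)
      fit <- twin_ace(pairs, c("trait1", "trait2"), model = "AE")
      c(fit$h2[[1]], fit$rg)
    })
    expect_equal(mean(est[1, ]), g$h2, tolerance = 0.05)
    expect_equal(mean(est[2, ]), g$rg, tolerance = 0.05)
  }
})

test_that("constrained fits are invariant to twin order and singletons
           contribute marginal terms", {
  gm <- twin_acemodel_std(h2 = 0.5)
  coh <- simulate_twin_cohort(twin_design(200, 200, 100), gm, seed = 61)
  fit <- twin_ace(coh$pairs, "trait1", model = "AE")
  perm <- permute_twin_order(coh$pairs, "trait1", seed = 7)
  fit2 <- twin_ace(perm, "trait1", model = "AE")
  expect_equal(fit$m2ll, fit2$m2ll, tolerance = 1e-6)
  expect_equal(unname(fit$h2), unname(fit2$h2), tolerance = 1e-5)
  # dropping the singletons changes the observed-value count accordingly
  fit_pairs_only <- twin_ace(coh$pairs[!coh$pairs$singleton, ],
                             "trait1", model = "AE")
  expect_equal(fit$n_obs - fit_pairs_only$n_obs, 100)
})

test_that("a single-zygosity table is refused as non-identifiable", {
  pairs <- toy_pairs(n_mz = 50, n_dz = 50, h2 = 0.5, seed = 62)
  expect_error(twin_ace(pairs[pairs$zygosity == "MZ", ], "trait1"),
               "identifiab")
})

test_that("fit and summary methods expose the standard modelling
           interface", {
  pairs <- toy_pairs(n_mz = 80, n_dz = 80, h2 = 0.5, seed = 63)
  fit <- twin_ace(pairs, "trait1", model = "AE")
  expect_s3_class(fit, "twin_ace")
  expect_output(print(fit), "Twin AE model")
  expect_named(coef(fit), c("trait1", "a2.trait1", "c2.trait1",
                            "e2.trait1"))
  ll <- logLik(fit)
  expect_equal(AIC(fit), fit$AIC)
  expect_equal(attr(ll, "df"), 3)
  sim <- simulate(fit, seed = 5)
  expect_true(all(c("trait1_1", "trait1_2") %in% names(sim)))
  an <- anova(fit, twin_ace(pairs, "trait1", model = "E"))
  expect_equal(an$d_df, 1)
})
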