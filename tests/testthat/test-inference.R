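# Likelihood-ratio tests, AIC, model selection, fit indices, profile CIs.

test_that("likelihood-ratio arithmetic follows the chi-square survival
           function", {
  expect_equal(lrt(list(m2ll = 100, ep = 4),
                   list(m2ll = 100, ep = 3))$p, 1)
  t2 <- lrt(list(m2ll = 100, ep = 4), list(m2ll = 103.841, ep = 3))
  expect_equal(t2$p, 0.05, tolerance = 1e-3)
  t3 <- lrt(list(m2ll = 4980.17, ep = 11),
            list(m2ll = 5173.55, ep = 5))
  expect_equal(t3$d_m2ll, 193.38, tolerance = 1e-10)
  expect_equal(t3$d_df, 6)
  expect_lt(t3$p, 0.001)
  expect_error(lrt(list(m2ll = 100, ep = 3), list(m2ll = 90, ep = 2)),
               "inconsistency")
  expect_error(lrt(list(m2ll = 100, ep = 3), list(m2ll = 90, ep = 3)),
               "fewer")
})

test_that("AIC is -2LL plus twice the parameter count", {
  expect_equal(aic_from_m2ll(4981.28, 8), 4997.28)
  expect_equal(aic_from_m2ll(2537.12, 3), 2543.12)
  expect_equal(aic_from_m2ll(0, 0), 0)
  expect_equal(aic_from_m2ll(list(m2ll = 10, ep = 2)), 14)
})

test_that("model selection prefers the lowest AIC with ties broken toward
           parsimony", {
  fits <- list(ACE = list(m2ll = 4980.17, ep = 11),
               AE = list(m2ll = 4981.28, ep = 8),
               CE = list(m2ll = 5001.96, ep = 8),
               E = list(m2ll = 5173.55, ep = 5))
  sel <- select_best(fits, full = fits$ACE)
  expect_equal(sel$best, "AE")
  expect_equal(unname(sel$aic),
               c(5002.17, 4997.28, 5017.96, 5183.55))
  tie <- select_best(list(a = list(m2ll = 10, ep = 4),
                          b = list(m2ll = 12, ep = 3)),
                     full = list(m2ll = 10, ep = 4))
  expect_equal(tie$best, "b")  # equal AIC 18, fewer parameters wins
  one <- select_best(list(only = list(m2ll = 5, ep = 1)))
  expect_equal(one$best, "only")
  expect_error(select_best(list()), "empty")
})

test_that("fit indices hit their definitional anchors", {
  sat <- list(m2ll = 100, ep = 10)
  ind <- list(m2ll = 190, ep = 4)
  same <- fit_indices(list(m2ll = 100, ep = 6), sat, ind, n_units = 300)
  expect_equal(same$chi2, 0)
  expect_equal(same$RMSEA, 0)
  expect_equal(same$CFI, 1)
  base <- fit_indices(ind, sat, ind, n_units = 300)
  expect_equal(base$CFI, 0)
})

test_that("a well-specified model keeps RMSEA below 0.05 and CFI high in
           simulation", {
  ok <- sapply(1:10, function(i) {
    pairs <- toy_pairs(n_mz = 400, n_dz = 400, h2 = 0.54,
                       seed = 800 + i)
    fit <- twin_ace(pairs, "trait1", model = "AE")
    sat <- twin_saturated(pairs, "trait1")
    ind <- twin_independence(pairs, "trait1")
    fi <- fit_indices(fit, sat, ind, n_units = fit$n_families)
    c(fi$RMSEA < 0.05, fi$CFI > 0.9)
  })
  expect_gte(mean(ok[1, ]), 0.9)
  expect_true(all(ok[2, ]))
})

test_that("the implied phenotypic correlation reduces correctly in its
           limiting cases", {
  mk <- function(a1, a2, rg, re) {
    e1 <- 1 - a1; e2 <- 1 - a2
    list(shares = rbind(a2 = c(a1, a2), c2 = c(0, 0), e2 = c(e1, e2)),
         rg = rg, rc = NA, re = re)
  }
  expect_equal(implied_phenotypic_correlation(mk(1, 1, 0.7, 0)), 0.7)
  # equal shares across traits with all correlations rho gives rho
  sh <- rbind(a2 = c(0.5, 0.5), c2 = c(0.2, 0.2), e2 = c(0.3, 0.3))
  expect_equal(implied_phenotypic_correlation(
    list(shares = sh, rg = 0.4, rc = 0.4, re = 0.4)), 0.4)
})

test_that("profile intervals contain the estimate, match Wald in the
           quadratic limit, and clip at natural bounds", {
  pairs <- toy_pairs(n_mz = 1500, n_dz = 1500, h2 = 0.54, seed = 65)
  fit <- twin_ace(pairs, "trait1", model = "AE")
  ci <- profile_ci(fit, "h2.trait1")
  expect_gte(ci$estimate, ci$lo)
  expect_lte(ci$estimate, ci$hi)
  expect_length(ci$clipped, 0)
  # interval roughly symmetric and narrow at this n (quadratic limit):
  # compare against a parametric-bootstrap SE
  half <- (ci$hi - ci$lo) / 2
  boots <- sapply(1:12, function(i) {
    bp <- simulate(fit, seed = 100 + i)
    unname(twin_ace(bp, "trait1", model = "AE")$h2)
  })
  expect_equal(half, 1.96 * sd(boots), tolerance = 0.25)
  # near-zero component: lower bound clipped at 0 and flagged
  pairs0 <- toy_pairs(n_mz = 400, n_dz = 400, h2 = 0, seed = 66)
  fit0 <- twin_ace(pairs0, "trait1", model = "ACE")
  ci0 <- profile_ci(fit0, "c2.trait1")
  expect_equal(ci0$lo, 0, tolerance = 1e-6)
  expect_true("lo" %in% ci0$clipped)
})

test_that("confint exposes profile intervals for correlations too", {
  pairs <- toy_pairs(n_mz = 300, n_dz = 300, h2 = c(0.54, 0.6),
                     rg = 0.46, re = 0.27, seed = 67)
  fit <- twin_ace(pairs, c("trait1", "trait2"), model = "AE")
  ci <- confint(fit, c("rg", "re"))
  expect_true(ci["rg", 1] <= fit$rg && fit$rg <= ci["rg", 2])
  expect_true(ci["re", 1] <= fit$re && fit$re <= ci["re", 2])
})
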