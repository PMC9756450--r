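# CKD filter, residualization, shift-log transform, IQR exclusion.

test_that("eGFR filtering removes exactly the below-threshold records and
           flags missing eGFR", {
  rec <- data.frame(subject = paste0("s", 1:4),
                    egfr = c(25, 31, NA, 90))
  out <- filter_ckd(rec, threshold = 30)
  expect_equal(out$excluded, "s1")
  expect_equal(nrow(out$kept), 3)
  expect_equal(out$missing_egfr, "s3")
  none <- filter_ckd(data.frame(egfr = c(35, 60)), 30)
  expect_length(none$excluded, 0)
})

test_that("five injected low-eGFR records are excluded by construction", {
  coh <- simulate_twin_cohort(twin_design(100, 80, 20), seed = 31)
  subj <- coh$subjects
  ok <- which(!is.na(subj$egfr) & subj$egfr > 40)
  low <- sample(ok, 5)
  subj$egfr[setdiff(which(subj$egfr < 30), low)] <- 45  # clean the rest
  subj$egfr[low] <- runif(5, 5, 29)
  out <- filter_ckd(subj, 30)
  expect_length(out$excluded, 5)
})

test_that("intercept-only residualization just demeans", {
  x <- c(4, 8, 1, 7)
  rz <- residualize(x, data.frame(row.names = seq_along(x)))
  expect_equal(rz$residuals, x - mean(x))
  expect_equal(rz$center, mean(x))
})

test_that("an exactly linear signal residualizes to zero", {
  z <- seq(-2, 3, length.out = 40)
  rz <- residualize(5 + 2.5 * z, data.frame(z = z))
  expect_lt(max(abs(rz$residuals)), 1e-10)
})

test_that("the 4-point worked example matches the normal-equations
           oracle", {
  y <- c(1, 3, 2, 5); z <- c(0, 1, 2, 3)
  # independent oracle: beta = (X'X)^-1 X'y via explicit matrix algebra
  X <- cbind(1, z)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  oracle_res <- as.numeric(y - X %*% beta)
  rz <- residualize(y, data.frame(z = z))
  expect_equal(rz$residuals, oracle_res, tolerance = 1e-12)
  expect_equal(rz$coefficients$beta, beta[2], tolerance = 1e-12)
})

test_that("residuals are orthogonal to every covariate column including
           one-hot encodings, and report t/p per term", {
  set.seed(17)
  n <- 120
  covs <- data.frame(age = rnorm(n, 70, 5),
                     grp = sample(c("a", "b", "c"), n, TRUE),
                     flag = sample(c(TRUE, FALSE), n, TRUE))
  y <- 2 + 0.3 * covs$age + (covs$grp == "b") + rnorm(n)
  rz <- residualize(y, covs)
  mm <- model.matrix(~ age + grp + flag,
                     transform(covs, grp = factor(grp)))
  for (j in 2:ncol(mm))
    expect_lt(abs(sum(rz$residuals * mm[, j])), 1e-8 * n)
  expect_lt(abs(sum(rz$residuals)), 1e-8 * n)
  expect_true(all(c("beta", "t", "p") %in% names(rz$coefficients)))
  # age is a strong covariate here
  expect_lt(rz$coefficients$p[rz$coefficients$term == "age"], 1e-6)
})

test_that("collinear covariates fail loudly with the column named", {
  z <- rnorm(30)
  expect_error(residualize(rnorm(30), data.frame(a = z, b = 2 * z)),
               "collinear.*b|b.*collinear")
})

test_that("missing covariates exclude rows listwise but keep vector
           length", {
  z <- c(rnorm(20), NA, NA)
  y <- rnorm(22)
  rz <- residualize(y, data.frame(z = z))
  expect_length(rz$residuals, 22)
  expect_true(all(is.na(rz$residuals[21:22])))
  expect_equal(rz$n_used, 20)
})

test_that("shift-log transform is exact on its fixed points and monotone", {
  expect_equal(shift_log_transform(rep(0, 5), recenter = 1), rep(0, 5))
  expect_equal(shift_log_transform(rep(0, 3), recenter = exp(1)),
               rep(1, 3))
  set.seed(2)
  x <- rnorm(50)
  y <- shift_log_transform(x, recenter = 10)
  expect_equal(cor(x, y, method = "spearman"), 1)
})

test_that("non-positive shifted values error with positions listed, never
           clipped", {
  expect_error(shift_log_transform(c(0.5, -2, 0.1), recenter = 1),
               "position\\(s\\): 2")
})

test_that("IQR filter reproduces the interpolation worked example and its
           boundary conventions", {
  fl <- iqr_upper_filter(c(1:8, 100), k = 3)
  expect_equal(fl$q3, 7)
  expect_equal(fl$iqr, 4)
  expect_equal(fl$threshold, 19)
  expect_equal(fl$excluded, 9L)
  # constant vector: zero IQR, nothing excluded
  expect_length(iqr_upper_filter(rep(2, 10))$excluded, 0)
  # exactly on the threshold is kept (strict inequality)
  fl2 <- iqr_upper_filter(c(1:8, 19), k = 3)
  expect_length(fl2$excluded, 0)
  expect_error(iqr_upper_filter(c(1, 2, 3)), "at least 4")
})

test_that("single-pass exclusion counts match a one-shot application", {
  set.seed(4)
  x <- c(rnorm(500), 25, 30, 40)
  fl <- iqr_upper_filter(x, k = 3)
  expect_equal(sort(fl$excluded), c(501L, 502L, 503L))
  # quartiles are computed once on the input: re-running on the kept set
  # is an explicit, separate call
  fl2 <- iqr_upper_filter(x[fl$keep], k = 3)
  expect_true(length(fl2$excluded) >= 0)  # distinct pass, own quartiles
})

test_that("the pipeline wrapper logs every exclusion by cause", {
  coh <- simulate_twin_cohort(twin_design(150, 100, 30), seed = 41)
  pp <- preprocess_biomarkers(
    coh$subjects,
    list(nfl = c("age", "bmi"), creatinine = c("age", "bmi")),
    egfr_threshold = 30, order = "log_first")
  expect_true(all(c("variable", "n_used", "iqr_excluded") %in%
                    names(pp$log)))
  expect_equal(nrow(pp$log), 2)
  expect_true(all(paste0(c("nfl", "creatinine"), "_adj") %in%
                    names(pp$data)))
})
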