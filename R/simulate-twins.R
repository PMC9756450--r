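# Seeded twin-cohort generator with exact ACE / correlated-factors latent
# structure. Latent draws are one multivariate-normal draw per family over
# the stacked additive-genetic, shared-environment and unique-environment
# factors with the Kronecker cross-twin/cross-trait correlation structure,
# so the implied pair covariances hold exactly (no rejection sampling).

#' Twin study design
#'
#' Family counts for [simulate_twin_cohort()]. Defaults mirror a VETSA-like
#' male twin cohort: 218 monozygotic pairs, 151 dizygotic pairs and 231
#' unpaired singletons (whose zygosity mix defaults to the paired-family
#' MZ share).
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons non-negative counts.
#' @param singleton_zygosity_mix proportion of singletons carrying MZ
#'   zygosity labels.
#' @export
twin_design <- function(n_mz_pairs = 218L, n_dz_pairs = 151L,
                        n_singletons = 231L,
                        singleton_zygosity_mix = n_mz_pairs /
                          max(n_mz_pairs + n_dz_pairs, 1L)) {
  d <- list(n_mz_pairs = as.integer(n_mz_pairs),
            n_dz_pairs = as.integer(n_dz_pairs),
            n_singletons = as.integer(n_singletons),
            singleton_zygosity_mix = singleton_zygosity_mix)
  if (any(unlist(d[1:3]) < 0L)) stop("design counts must be non-negative")
  if (singleton_zygosity_mix < 0 || singleton_zygosity_mix > 1)
    stop("singleton_zygosity_mix must be in [0, 1]")
  structure(d, class = "twin_design")
}

#' Generating model for a twin cohort
#'
#' Raw per-trait variance components, cross-trait factor correlations,
#' means, covariate effects and missingness rates. The default is
#' calibrated to the VETSA biomarker panel: plasma NfL (ng/L, mean 13.18,
#' SD 6.88, h2 = 0.54) and serum creatinine (mg/dL, mean 1.04, SD 0.21,
#' h2 = 0.60) under a bivariate AE structure with genetic correlation 0.46
#' and unique-environment correlation 0.27; covariate slopes (age, BMI,
#' ethnicity) are the reported regression coefficients, and creatinine is
#' missing completely at random at the observed 33/969 rate.
#'
#' The A/C/E values describe the covariate-adjusted scale: covariate
#' effects are added on top, so raw phenotypes must be residualized before
#' the components are recovered.
#'
#' @param traits trait names (1 or 2).
#' @param A,C,E named raw variance components per trait (non-negative;
#'   E = 0 yields degenerate within-pair distributions that only make
#'   sense for generator checks, not for fitting).
#' @param rg,rc,re cross-trait factor correlations in \[-1, 1\].
#' @param means per-trait means.
#' @param covariates list of covariate specs; each is a list with `level`
#'   (`"family"` or `"individual"`), `type` (`"normal"` or `"binary"`),
#'   `mean`/`sd` or `prob`, and `slopes` (named per trait). Effects are
#'   centred so trait means are unchanged.
#' @param missing named per-trait MCAR missingness proportions.
#' @param outlier_rate,outlier_magnitude optional contamination passed to
#'   [inject_outliers()] per trait (defaults off).
#' @param observed `"identity"` (phenotype = latent scale) or `"exp"`
#'   (phenotypes are exponentiated, giving strictly positive, right-skewed
#'   biomarker values whose log scale carries the exact ACE structure; the
#'   default VETSA model uses this, with A/C/E, means and slopes expressed
#'   on the log scale so the analysis pipeline's log transform recovers
#'   them).
#' @export
twin_acemodel <- function(
    traits = c("nfl", "creatinine"),
    A = c(nfl = 0.54 * lognorm_var(13.18, 6.88),
          creatinine = 0.60 * lognorm_var(1.04, 0.21)),
    C = c(nfl = 0, creatinine = 0),
    E = c(nfl = 0.46 * lognorm_var(13.18, 6.88),
          creatinine = 0.40 * lognorm_var(1.04, 0.21)),
    rg = 0.46, rc = 0, re = 0.27,
    means = c(nfl = lognorm_mean(13.18, 6.88),
              creatinine = lognorm_mean(1.04, 0.21)),
    covariates = if (identical(traits, c("nfl", "creatinine")))
      vetsa_covariates() else list(),
    missing = if (identical(traits, c("nfl", "creatinine")))
      c(nfl = 0, creatinine = 33 / 969) else
      stats::setNames(rep(0, length(traits)), traits),
    outlier_rate = 0, outlier_magnitude = 10,
    observed = if (identical(traits, c("nfl", "creatinine"))) "exp"
               else "identity") {
  k <- length(traits)
  norm <- function(x, default = 0) {
    if (is.null(names(x))) x <- stats::setNames(rep_len(x, k), traits)
    out <- stats::setNames(rep(default, k), traits)
    out[names(x)] <- x
    out
  }
  m <- structure(list(traits = traits, A = norm(A), C = norm(C),
                      E = norm(E), rg = rg, rc = rc, re = re,
                      means = norm(means), covariates = covariates,
                      missing = norm(missing),
                      outlier_rate = outlier_rate,
                      outlier_magnitude = outlier_magnitude,
                      observed = match.arg(observed,
                                           c("identity", "exp"))),
                 class = "twin_acemodel")
  validate_acemodel(m)
  m
}

#' @rdname twin_acemodel
#' @param h2,c2 standardized shares per trait (unit total variance); a
#'   convenience constructor for recovery studies on the standardized
#'   scale, with no covariate effects or missingness.
#' @export
twin_acemodel_std <- function(h2, c2 = 0, rg = 0, rc = 0, re = 0) {
  k <- length(h2)
  c2 <- rep_len(c2, k)
  traits <- paste0("trait", seq_len(k))
  twin_acemodel(traits = traits,
                A = stats::setNames(h2, traits),
                C = stats::setNames(c2, traits),
                E = stats::setNames(1 - h2 - c2, traits),
                rg = rg, rc = rc, re = re,
                means = stats::setNames(rep(0, k), traits),
                covariates = list(),
                missing = stats::setNames(rep(0, k), traits),
                observed = "identity")
}

# log-normal scale parameters matching a natural-scale mean and SD
lognorm_var <- function(m, s) log(1 + (s / m)^2)
lognorm_mean <- function(m, s) log(m) - lognorm_var(m, s) / 2

# default VETSA-like covariate structure; slopes are the reported raw-unit
# regression coefficients converted to the log scale (divided by the trait
# mean); storage time in months is a design choice
vetsa_covariates <- function() {
  list(
    age = list(level = "family", type = "normal", mean = 67.57,
               sd = 2.52, slopes = c(nfl = 0.28 / 13.18)),
    bmi = list(level = "individual", type = "normal", mean = 29.93,
               sd = 5.20, slopes = c(nfl = -0.12 / 13.18,
                                     creatinine = 0.003 / 1.04)),
    ethnicity_white = list(level = "family", type = "binary",
                           prob = 0.91,
                           slopes = c(creatinine = -0.07 / 1.04)),
    same_day = list(level = "family", type = "binary", prob = 0.5,
                    slopes = numeric(0)),
    site2 = list(level = "family", type = "binary", prob = 0.5,
                 slopes = numeric(0)),
    storage_time = list(level = "individual", type = "normal",
                        mean = 24, sd = 6, slopes = numeric(0)))
}

validate_acemodel <- function(m) {
  if (any(m$A < 0) || any(m$C < 0) || any(m$E < 0))
    stop("variance components must be non-negative")
  if (any(abs(c(m$rg, m$rc, m$re)) > 1))
    stop("|rg|, |rc|, |re| must not exceed 1")
  for (z in c("MZ", "DZ")) {
    sg <- ace_expected_cov(m$A, m$C, m$E, zygosity = z,
                           rg = m$rg, rc = m$rc, re = m$re)
    ev <- eigen(sg, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      stop("implied ", z, " pair covariance block is not positive ",
           "semidefinite (min eigenvalue ", signif(min(ev), 3), ")")
  }
  invisible(m)
}

# exact MVN draw tolerating singular covariance (MZ additive-genetic block)
rmvn_psd <- function(n, sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * ncol(sigma)), n)
  z %*% t(e$vectors %*% diag(sqrt(lam), ncol(sigma)))
}

#' Simulate a twin cohort with known ACE structure
#'
#' Draws, for each family, stacked additive-genetic factors with cross-twin
#' correlation 1.0 (MZ) or 0.5 (DZ) and cross-trait correlation `rg`,
#' shared-environment factors common to the pair with cross-trait
#' correlation `rc`, and unique-environment factors independent across
#' twins with cross-trait correlation `re`; adds means and centred
#' covariate effects; applies MCAR missingness and optional outlier
#' contamination; randomizes twin order within pairs; and generates
#' singletons as full pairs with one twin's record dropped (preserving the
#' marginal distribution of observed twins).
#'
#' @param design a [twin_design()].
#' @param model a [twin_acemodel()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return list of class `twin_cohort`: `pairs` (wide pair table with
#'   `family`, `zygosity`, `singleton`, `<trait>_1`, `<trait>_2`),
#'   `subjects` (long per-person table with covariates and, for the
#'   default biomarker model, an `egfr` column), `model` and `design`
#'   echoes, `seed`, and `outliers` (injected indices per trait, if any).
#' @export
simulate_twin_cohort <- function(design = twin_design(),
                                 model = twin_acemodel(),
                                 seed = 1L) {
  stopifnot(inherits(design, "twin_design"),
            inherits(model, "twin_acemodel"))
  validate_acemodel(model)
  set.seed(as.integer(seed))
  k <- length(model$traits)
  n_single_mz <- round(design$n_singletons * design$singleton_zygosity_mix)
  fam <- data.frame(
    zygosity = c(rep("MZ", design$n_mz_pairs),
                 rep("DZ", design$n_dz_pairs),
                 rep("MZ", n_single_mz),
                 rep("DZ", design$n_singletons - n_single_mz)),
    singleton = c(rep(FALSE, design$n_mz_pairs + design$n_dz_pairs),
                  rep(TRUE, design$n_singletons)),
    stringsAsFactors = FALSE)
  n_fam <- nrow(fam)
  if (n_fam == 0L) stop("design has no families")
  fam$family <- seq_len(n_fam)
  # phenotype latent part: columns (twin1 traits, twin2 traits)
  pheno <- matrix(NA_real_, n_fam, 2L * k)
  fc <- function(v, r) {
    if (k == 1L) matrix(v, 1L, 1L)
    else matrix(c(v[1L], r * sqrt(v[1L] * v[2L]),
                  r * sqrt(v[1L] * v[2L]), v[2L]), 2L)
  }
  SA <- fc(model$A, model$rg); SC <- fc(model$C, model$rc)
  SE <- fc(model$E, model$re)
  for (z in c("MZ", "DZ")) {
    idx <- which(fam$zygosity == z)
    if (!length(idx)) next
    ra <- if (z == "MZ") 1 else 0.5
    Ablock <- kronecker(matrix(c(1, ra, ra, 1), 2L), SA)
    Adraw <- rmvn_psd(length(idx), Ablock)
    Cdraw <- rmvn_psd(length(idx), SC)
    Edraw <- cbind(rmvn_psd(length(idx), SE), rmvn_psd(length(idx), SE))
    pheno[idx, ] <- Adraw + cbind(Cdraw, Cdraw) + Edraw
  }
  pheno <- sweep(pheno, 2L, rep(model$means, 2L), "+")
  # covariates: family-level shared by the pair, individual-level per twin
  cov_vals <- list()
  for (cn in names(model$covariates)) {
    sp <- model$covariates[[cn]]
    draw <- function(n) {
      if (identical(sp$type, "binary")) stats::rbinom(n, 1L, sp$prob)
      else stats::rnorm(n, sp$mean, sp$sd)
    }
    centre <- if (identical(sp$type, "binary")) sp$prob else sp$mean
    v <- if (identical(sp$level, "family")) {
      x <- draw(n_fam); cbind(x, x)
    } else cbind(draw(n_fam), draw(n_fam))
    cov_vals[[cn]] <- v
    for (tr in names(sp$slopes)) {
      ti <- match(tr, model$traits)
      if (is.na(ti)) next
      for (tw in 1:2)
        pheno[, (tw - 1L) * k + ti] <- pheno[, (tw - 1L) * k + ti] +
          sp$slopes[[tr]] * (v[, tw] - centre)
    }
  }
  if (identical(model$observed, "exp")) pheno <- exp(pheno)
  # MCAR missingness
  for (ti in seq_len(k)) {
    rate <- model$missing[[ti]]
    if (rate > 0) for (tw in 1:2) {
      j <- (tw - 1L) * k + ti
      pheno[stats::runif(n_fam) < rate, j] <- NA_real_
    }
  }
  # outlier contamination (per trait, across both twins jointly)
  outliers <- list()
  if (model$outlier_rate > 0) for (ti in seq_len(k)) {
    cols <- c(ti, k + ti)
    vals <- as.vector(pheno[, cols])
    inj <- inject_outliers(vals, rate = model$outlier_rate,
                           magnitude = model$outlier_magnitude,
                           seed = as.integer(seed) + ti)
    pheno[, cols] <- matrix(inj$values, ncol = 2L)
    outliers[[model$traits[ti]]] <- inj$index
  }
  # randomize twin order, then drop one twin from singleton families
  swap <- stats::runif(n_fam) < 0.5
  pheno[swap, ] <- pheno[swap, c((k + 1L):(2L * k), 1:k), drop = FALSE]
  for (cn in names(cov_vals))
    cov_vals[[cn]][swap, ] <- cov_vals[[cn]][swap, 2:1, drop = FALSE]
  drop2 <- fam$singleton
  pheno[drop2, (k + 1L):(2L * k)] <- NA_real_
  pairs <- data.frame(family = fam$family, zygosity = fam$zygosity,
                      singleton = fam$singleton)
  for (tw in 1:2) for (ti in seq_len(k))
    pairs[[paste0(model$traits[ti], "_", tw)]] <-
      pheno[, (tw - 1L) * k + ti]
  # long subject table
  subj <- do.call(rbind, lapply(1:2, function(tw) {
    d <- data.frame(family = fam$family, zygosity = fam$zygosity,
                    singleton = fam$singleton, order = tw)
    for (ti in seq_len(k))
      d[[model$traits[ti]]] <- pheno[, (tw - 1L) * k + ti]
    for (cn in names(cov_vals)) d[[cn]] <- cov_vals[[cn]][, tw]
    d
  }))
  subj <- subj[!(subj$order == 2L & subj$singleton), ]
  subj <- subj[order(subj$family, subj$order), ]
  subj$subject <- paste0("S", subj$family, "_", subj$order)
  subj$sex <- "male"
  # eGFR derived from creatinine for the biomarker default
  if ("creatinine" %in% model$traits) {
    zc <- as.vector(scale(subj$creatinine))
    zc[is.na(zc)] <- 0
    subj$egfr <- 75.43 + 13.79 * (-0.65 * zc +
      sqrt(1 - 0.65^2) * stats::rnorm(nrow(subj)))
    subj$egfr[stats::runif(nrow(subj)) < 33 / 969] <- NA_real_
  }
  rownames(subj) <- NULL
  structure(list(pairs = pairs, subjects = subj, model = model,
                 design = design, seed = as.integer(seed),
                 outliers = outliers),
            class = "twin_cohort")
}

#' Write a simulated cohort to CSV with a JSON parameter sidecar
#'
#' @param cohort a [simulate_twin_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "twin_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pairs = file.path(dir, "pairs.csv"),
             subjects = file.path(dir, "subjects.csv"),
             params = file.path(dir, "params.json"))
  utils::write.csv(cohort$pairs, paths[["pairs"]], row.names = FALSE)
  utils::write.csv(cohort$subjects, paths[["subjects"]], row.names = FALSE)
  # named numeric vectors become JSON objects, and 17 significant digits
  # make the parameter echo round-trip bit-identically
  to_jsonable <- function(x) {
    if (is.list(x)) lapply(x, to_jsonable)
    else if (!is.null(names(x)) && length(x)) as.list(x)
    else x
  }
  jsonlite::write_json(
    list(model = to_jsonable(unclass(cohort$model)),
         design = to_jsonable(unclass(cohort$design)),
         seed = cohort$seed),
    paths[["params"]], auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(paths)
}
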