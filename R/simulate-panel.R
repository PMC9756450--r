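# ADNI-like biomarker panel generator: plasma NfL shares a neurodegeneration
# factor with CSF NfL and brain volumes (negative loadings) and a separate
# renal factor with serum creatinine; the two factors are orthogonal, so the
# variance plasma NfL shares with creatinine is independent of the variance
# it shares with CSF NfL, and creatinine adjustment leaves the NfL-CSF and
# NfL-volume correlations essentially unchanged.

#' Generating model for an ADNI-like biomarker panel
#'
#' Markers load on two orthogonal standard-normal latents: a
#' neurodegeneration factor (plasma NfL, CSF NfL positively; hippocampal,
#' medial-temporal and whole-brain volumes negatively) and a renal factor
#' (plasma NfL and serum creatinine only — its loading on CSF NfL and
#' volumes is structurally zero). A body-size latent links the volumes to
#' intracranial volume. Marker scales (means, SDs) default to the ADNI
#' sample characteristics: plasma NfL 38.94 (26.02) ng/L, CSF NfL 1387
#' (1038) pg/mL, creatinine 0.98 (0.24) mg/dL; volume scales are realistic
#' FreeSurfer values. Covariate effects default to the reported
#' age and BMI slopes, with sex mean-shifts for creatinine and CSF NfL;
#' missingness defaults to the observed per-marker rates (e.g. CSF NfL
#' 96/393).
#'
#' @param loadings named list of standardized loadings per marker:
#'   `neuro`, `renal`, `body` entries (absent = 0); unique variance is the
#'   complement of the squared loadings.
#' @param scale named list of `c(mean, sd)` per marker.
#' @param sex_effect named per-marker additive male effect (on the raw
#'   scale; the panel draws sex male with probability `p_male`).
#' @param age_slope,bmi_slope named per-marker slopes (raw units per year
#'   / per kg/m2), centred so marker means are unchanged.
#' @param p_male probability of male sex.
#' @param missing named per-marker missingness proportions (MCAR).
#' @export
panel_model <- function(
    loadings = list(
      plasma_nfl = c(neuro = 0.70, renal = 0.33),
      csf_nfl = c(neuro = 0.75),
      creatinine = c(renal = 0.80),
      hippocampus = c(neuro = -0.30, body = 0.45),
      mtl_volume = c(neuro = -0.17, body = 0.50),
      whole_brain = c(neuro = -0.31, body = 0.60),
      icv = c(body = 0.90)),
    scale = list(
      plasma_nfl = c(38.94, 26.02), csf_nfl = c(1387.13, 1037.74),
      creatinine = c(0.98, 0.24), hippocampus = c(6800, 900),
      mtl_volume = c(21500, 2600), whole_brain = c(1000000, 100000),
      icv = c(1500000, 150000)),
    sex_effect = c(creatinine = 0.25, csf_nfl = 280, icv = 150000,
                   whole_brain = 90000, hippocampus = 350,
                   mtl_volume = 1400),
    age_slope = c(plasma_nfl = 0.99, csf_nfl = 28.20,
                  creatinine = 0.01, hippocampus = -45,
                  mtl_volume = -110, whole_brain = -4500),
    bmi_slope = c(plasma_nfl = -0.95, creatinine = 0.01),
    p_male = 236 / 393,
    missing = c(plasma_nfl = 7 / 393, csf_nfl = 96 / 393,
                creatinine = 0, hippocampus = 0.05, mtl_volume = 0.05,
                whole_brain = 0.05, icv = 0.05)) {
  for (mk in names(loadings)) {
    l2 <- sum(loadings[[mk]]^2)
    if (l2 > 1) stop("squared loadings for '", mk, "' exceed 1")
    if (any(unlist(scale[[mk]]) < 0) || scale[[mk]][2L] <= 0)
      stop("invalid scale for '", mk, "'")
  }
  cz <- vapply(loadings, function(l)
    if ("renal" %in% names(l)) l[["renal"]] else 0, numeric(1L))
  bad <- names(loadings)[cz != 0 &
                           !names(loadings) %in% c("plasma_nfl",
                                                   "creatinine")]
  if (length(bad))
    stop("the renal factor may load only on plasma NfL and creatinine ",
         "(offending: ", paste(bad, collapse = ", "), ")")
  structure(list(loadings = loadings, scale = scale,
                 sex_effect = sex_effect, age_slope = age_slope,
                 bmi_slope = bmi_slope, p_male = p_male,
                 missing = missing),
            class = "panel_model")
}

#' Simulate an ADNI-like biomarker panel
#'
#' @param n number of subjects (at least 3).
#' @param model a [panel_model()].
#' @param seed integer seed.
#' @return data frame with one row per subject: `subject`, `sex`, `age`,
#'   `bmi`, `ethnicity`, `egfr`, `mci`, and one column per marker.
#' @export
simulate_biomarker_panel <- function(n, model = panel_model(),
                                     seed = 1L) {
  stopifnot(inherits(model, "panel_model"))
  if (n < 3L) stop("n < 3: no estimable correlation")
  set.seed(as.integer(seed))
  neuro <- stats::rnorm(n); renal <- stats::rnorm(n)
  body <- stats::rnorm(n)
  sex <- ifelse(stats::runif(n) < model$p_male, "male", "female")
  age <- stats::rnorm(n, 75.22, 6.35)
  bmi <- stats::rnorm(n, 26.24, 3.99)
  ethnicity <- ifelse(stats::runif(n) < 0.93, "white-non-hispanic",
                      "other")
  mci <- stats::runif(n) < 0.51
  out <- data.frame(subject = sprintf("P%04d", seq_len(n)), sex = sex,
                    age = age, bmi = bmi, ethnicity = ethnicity,
                    mci = mci, stringsAsFactors = FALSE)
  lat <- cbind(neuro = neuro, renal = renal, body = body)
  # markers are log-normal: the factor structure and covariate effects sit
  # on the log scale (raw-unit slopes are converted by dividing by the
  # marker mean), keeping values strictly positive and right-skewed while
  # the designed correlations hold exactly after a log transform
  for (mk in names(model$loadings)) {
    l <- model$loadings[[mk]]
    z <- rep(0, n)
    for (f in names(l)) z <- z + l[[f]] * lat[, f]
    uniq <- sqrt(max(1 - sum(l^2), 0))
    z <- z + uniq * stats::rnorm(n)
    sc <- model$scale[[mk]]
    sig <- sqrt(log(1 + (sc[2L] / sc[1L])^2))
    lv <- log(sc[1L]) - sig^2 / 2 + sig * z
    se <- model$sex_effect[mk]
    if (!is.na(se))
      lv <- lv + (ifelse(sex == "male", 1, 0) - model$p_male) *
        se / sc[1L]
    as_ <- model$age_slope[mk]
    if (!is.na(as_)) lv <- lv + as_ / sc[1L] * (age - 75.22)
    bs <- model$bmi_slope[mk]
    if (!is.na(bs)) lv <- lv + bs / sc[1L] * (bmi - 26.24)
    v <- exp(lv)
    rate <- model$missing[mk]
    if (!is.na(rate) && rate > 0)
      v[stats::runif(n) < rate] <- NA_real_
    out[[mk]] <- v
  }
  # eGFR tracks the renal factor inversely (it is an input downstream, not
  # computed from creatinine by any estimating equation)
  out$egfr <- 69.77 + 14.8 * (-0.65 * renal +
    sqrt(1 - 0.65^2) * stats::rnorm(n))
  out$egfr[stats::runif(n) < 2 / 393] <- NA_real_
  out
}
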