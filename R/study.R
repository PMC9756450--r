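# End-to-end study runners: the two-stage workflow on an ADNI-like
# biomarker panel (correlations before/after creatinine adjustment) and a
# VETSA-like twin cohort (homogeneity testing, ACE-family fits, genetic /
# environmental correlations).

#' Run the biomarker-panel correlation study
#'
#' Executes the fixed pipeline on an ADNI-like subject table: eGFR filter,
#' per-variable covariate residualization (biomarkers on age, ethnicity,
#' BMI; brain volumes on age, ethnicity, sex and intracranial volume),
#' shift-log transform, one-sided IQR filter; then the correlation report
#' of plasma NfL against CSF NfL, creatinine and each volume, in the full
#' sample and by sex, with and without creatinine adjustment.
#'
#' Sex is deliberately not a residualization covariate for the biomarkers
#' (the analysis stratifies by sex instead); it is one for the volumes.
#'
#' @param panel subject-level data frame (see
#'   [simulate_biomarker_panel()]); must contain `plasma_nfl`, `csf_nfl`,
#'   `creatinine`, the volume columns, `egfr`, `sex`, `age`, `bmi`,
#'   `ethnicity`.
#' @param out optional directory; when given, writes `table3.tsv`,
#'   `run_log.json` and `coefficients.tsv`.
#' @param k IQR multiplier.
#' @param egfr_threshold CKD exclusion threshold.
#' @return list with `table` (the correlation report), `exclusions`
#'   (counts by cause), `coefficients`, `n_analyzed`, `config_hash`.
#' @export
run_study1 <- function(panel, out = NULL, k = 3, egfr_threshold = 30) {
  need <- c("plasma_nfl", "csf_nfl", "creatinine", "hippocampus",
            "mtl_volume", "whole_brain", "icv", "egfr", "sex", "age",
            "bmi", "ethnicity")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing required column(s): ",
         paste(miss, collapse = ", "))
  bio_covs <- c("age", "ethnicity", "bmi")
  vol_covs <- c("age", "ethnicity", "sex", "icv")
  vars <- list(plasma_nfl = bio_covs, csf_nfl = bio_covs,
               creatinine = bio_covs,
               hippocampus = vol_covs, mtl_volume = vol_covs,
               whole_brain = vol_covs)
  pp <- preprocess_biomarkers(panel, vars, egfr_threshold = egfr_threshold,
                              k = k, order = "log_first")
  d <- pp$data
  prs <- list(c("plasma_nfl_adj", "csf_nfl_adj"),
              c("plasma_nfl_adj", "creatinine_adj"),
              c("plasma_nfl_adj", "hippocampus_adj"),
              c("plasma_nfl_adj", "mtl_volume_adj"),
              c("plasma_nfl_adj", "whole_brain_adj"))
  tab <- correlation_table(d, prs, strata = "sex",
                           adjusters = "creatinine_adj")
  cfg <- list(k = k, egfr_threshold = egfr_threshold,
              covariates = vars)
  res <- list(table = tab,
              exclusions = rbind(
                data.frame(variable = "egfr", n_used = NA,
                           missing_covariates = NA,
                           iqr_excluded = length(pp$ckd_excluded)),
                pp$log),
              coefficients = pp$coefficients,
              n_analyzed = nrow(d),
              config_hash = config_hash(cfg))
  if (!is.null(out)) write_study_reports(res, out, "study1")
  res
}

#' Run the twin biometrical study
#'
#' On a VETSA-like cohort: preprocesses the biomarkers (residualization on
#' age, ethnicity, BMI and same-day flag, NfL additionally on site and
#' storage time; shift-log; IQR filter), reassembles the pair table, then
#' per trait computes twin correlations by zygosity, the mean/variance
#' homogeneity sequence, and univariate ACE/AE/CE/E fits, followed by the
#' bivariate correlated-factors fits with AIC/likelihood-ratio model
#' selection and the implied phenotypic correlation of the best model.
#'
#' @param cohort a [simulate_twin_cohort()] result, or a list with
#'   `subjects` (long table incl. `family`, `zygosity`, `order`) for the
#'   two traits below.
#' @param traits two trait column names.
#' @param preprocess logical; set `FALSE` when the traits are already
#'   residualized.
#' @param ci compute profile CIs for the best bivariate model's h2 and
#'   correlations (slower).
#' @param out optional output directory (`table4.tsv`, `table5.tsv`,
#'   `results.json`).
#' @return list with `twin_correlations`, `homogeneity` (per trait),
#'   `univariate` (per trait model tables), `bivariate` (model table),
#'   `best` (name + fit + components + implied r + optional CIs),
#'   `exclusions`, `config_hash`.
#' @export
run_study2 <- function(cohort, traits = c("nfl", "creatinine"),
                       preprocess = TRUE, ci = FALSE, out = NULL) {
  subj <- if (inherits(cohort, "twin_cohort")) cohort$subjects
          else cohort$subjects %||% cohort
  miss <- setdiff(c("family", "zygosity", "order", traits), names(subj))
  if (length(miss))
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (length(unique(subj$zygosity)) < 2L)
    stop("cohort contains a single zygosity group: additive-genetic and ",
         "shared-environment variance are not separately identifiable")
  exclusions <- NULL
  if (preprocess) {
    base_covs <- intersect(c("age", "ethnicity_white", "bmi",
                             "same_day"), names(subj))
    nfl_covs <- c(base_covs, intersect(c("site2", "storage_time"),
                                       names(subj)))
    vars <- stats::setNames(list(nfl_covs, base_covs), traits)
    pp <- preprocess_biomarkers(subj, vars,
                                egfr_threshold =
                                  if ("egfr" %in% names(subj)) 30
                                  else NULL,
                                order = "log_first")
    subj <- pp$data
    exclusions <- pp$log
    traits_use <- paste0(traits, "_adj")
  } else traits_use <- traits
  pairs <- subjects_to_pairs(subj, traits_use)
  names(pairs) <- sub("_adj_", "_", names(pairs))
  res <- list(exclusions = exclusions)
  res$twin_correlations <- do.call(rbind, lapply(traits, function(tr)
    cbind(trait = tr, twin_correlations(pairs, tr))))
  res$homogeneity <- lapply(stats::setNames(traits, traits),
                            function(tr) homogeneity_sequence(pairs, tr))
  res$univariate <- lapply(stats::setNames(traits, traits), function(tr)
    twin_ace_models(pairs, tr))
  biv <- twin_ace_models(pairs, traits)
  res$bivariate <- biv
  best_fit <- biv$fits[[biv$best]]
  res$best <- list(model = biv$best, fit = best_fit,
                   shares = best_fit$shares, h2 = best_fit$h2,
                   rg = best_fit$rg, rc = best_fit$rc, re = best_fit$re,
                   implied_r = best_fit$implied_r)
  if (ci) {
    qs <- c(paste0("h2.", traits),
            intersect(c("rg", "rc", "re"), names(coef(best_fit))))
    res$best$ci <- lapply(stats::setNames(qs, qs), function(q)
      profile_ci(best_fit, q))
  }
  res$config_hash <- config_hash(list(traits = traits,
                                      preprocess = preprocess))
  if (!is.null(out)) write_study_reports(res, out, "study2")
  res
}

#' Reshape a long subject table into the wide pair table
#'
#' @param subjects long table with `family`, `zygosity`, `order` and trait
#'   columns.
#' @param traits trait column names to widen.
#' @return pair table with `<trait>_1`, `<trait>_2` per family.
#' @export
subjects_to_pairs <- function(subjects, traits) {
  fams <- unique(subjects[c("family", "zygosity")])
  fams <- fams[order(fams$family), , drop = FALSE]
  out <- fams
  for (tr in traits) for (tw in 1:2) {
    sel <- subjects[subjects$order == tw, c("family", tr)]
    out[[paste0(tr, "_", tw)]] <-
      sel[[tr]][match(out$family, sel$family)]
  }
  rownames(out) <- NULL
  out
}

write_study_reports <- function(res, out, prefix) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config_hash = res$config_hash,
               package_version =
                 as.character(utils::packageVersion("twinace")))
  if (identical(prefix, "study1")) {
    utils::write.table(res$table, file.path(out, "table3.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    coefs <- do.call(rbind, lapply(names(res$coefficients), function(v)
      cbind(variable = v, res$coefficients[[v]])))
    utils::write.table(coefs, file.path(out, "coefficients.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(c(meta, list(
      n_analyzed = res$n_analyzed,
      exclusions = res$exclusions)),
      file.path(out, "run_log.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  } else {
    t4 <- do.call(rbind, lapply(names(res$homogeneity), function(tr)
      cbind(trait = tr, res$homogeneity[[tr]]$table)))
    utils::write.table(t4, file.path(out, "table4.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    t5u <- do.call(rbind, lapply(names(res$univariate), function(tr)
      cbind(scope = tr, res$univariate[[tr]]$table)))
    t5 <- rbind(cbind(scope = "bivariate", res$bivariate$table), t5u)
    t5$best <- t5$scope == "bivariate" & t5$model == res$bivariate$best
    utils::write.table(t5, file.path(out, "table5.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(c(meta, list(
      best_model = res$best$model,
      h2 = as.list(res$best$h2),
      rg = res$best$rg, rc = res$best$rc, re = res$best$re,
      implied_r = res$best$implied_r,
      twin_correlations = res$twin_correlations)),
      file.path(out, "results.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  invisible(out)
}
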