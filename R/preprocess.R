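# Preprocessing pipeline: chronic-kidney-disease filter, covariate
# residualization, shift-log transform, one-sided IQR outlier exclusion.
# The pipeline order is fixed: CKD filter -> residualize -> shift-log ->
# IQR filter.

#' Exclude subjects with severe chronic kidney disease
#'
#' Removes records whose estimated glomerular filtration rate falls below
#' the stage-4 threshold (eGFR < 30 mL/min/1.73 m2 by default); records
#' with missing eGFR are kept and flagged.
#'
#' @param records data frame with an `egfr` column.
#' @param threshold exclusion threshold (eGFR strictly below is removed).
#' @return list with `kept` (data frame), `excluded` (row identifiers —
#'   the `subject` column if present, else row indices), and
#'   `missing_egfr` (identifiers of kept records lacking eGFR).
#' @export
filter_ckd <- function(records, threshold = 30) {
  if (threshold <= 0) stop("'threshold' must be positive")
  if (!"egfr" %in% names(records)) stop("'records' needs an 'egfr' column")
  id <- records[["subject"]] %||% seq_len(nrow(records))
  drop <- !is.na(records$egfr) & records$egfr < threshold
  list(kept = records[!drop, , drop = FALSE],
       excluded = id[drop],
       missing_egfr = id[!drop & is.na(records$egfr)])
}

#' Residualize a variable on covariates by ordinary least squares
#'
#' Regresses `values` on an intercept plus the supplied covariates and
#' returns the residuals together with the per-covariate slope, t statistic
#' and p value. Categorical covariates are one-hot encoded with the most
#' frequent level as the reference. Rows with a missing value or missing
#' covariate are excluded listwise from the regression (their residual is
#' `NA`). For twin data both twins are stacked into the one regression so
#' the coefficients are shared across the pair (pass `by` to fit separate
#' regressions per group instead).
#'
#' @param values numeric vector.
#' @param covariates data frame (or matrix) of covariates, same length.
#' @param by optional grouping vector for separate per-group regressions.
#' @return object of class `residualization`: `residuals` (same length as
#'   the input, `NA` where excluded), `coefficients` (term, beta, t, p),
#'   `intercept`, `n_used`, `center` (the sample mean of the included raw
#'   values — the default recentering constant for
#'   [shift_log_transform()]).
#' @export
residualize <- function(values, covariates, by = NULL) {
  if (!is.null(by)) {
    res <- rep(NA_real_, length(values))
    groups <- split(seq_along(values), by)
    fits <- lapply(groups, function(ix)
      residualize(values[ix], covariates[ix, , drop = FALSE]))
    for (g in names(groups))
      res[groups[[g]]] <- fits[[g]]$residuals
    out <- fits[[1L]]
    out$residuals <- res
    out$by_group <- fits
    return(out)
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(values))
    stop("'covariates' must have one row per value")
  for (j in seq_along(covariates)) {
    cj <- covariates[[j]]
    if (is.character(cj) || is.factor(cj) || is.logical(cj))
      covariates[[j]] <- relevel_by_frequency(cj)
  }
  use <- !is.na(values) & stats::complete.cases(covariates)
  n_used <- sum(use)
  if (n_used <= ncol(covariates) + 1L)
    stop("need more observations than covariates")
  mm <- if (ncol(covariates) == 0L) matrix(1, n_used, 1L,
                                           dimnames = list(NULL,
                                                           "(Intercept)"))
        else stats::model.matrix(~ .,
                                 data = covariates[use, , drop = FALSE])
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[setdiff(seq_len(ncol(mm)),
                                qr_mm$pivot[seq_len(qr_mm$rank)])]
    stop("rank-deficient covariate matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(mm, values[use])
  rdf <- n_used - ncol(mm)
  s2 <- sum(fit$residuals^2) / rdf
  xtx_inv <- solve(crossprod(mm))
  se <- sqrt(s2 * diag(xtx_inv))
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(abs(tval), rdf, lower.tail = FALSE)
  res <- rep(NA_real_, length(values))
  res[use] <- fit$residuals
  structure(list(
    residuals = res,
    coefficients = data.frame(term = colnames(mm)[-1L],
                              beta = unname(fit$coefficients[-1L]),
                              t = unname(tval[-1L]),
                              p = unname(pval[-1L])),
    intercept = unname(fit$coefficients[1L]),
    n_used = n_used,
    center = mean(values[use])),
    class = "residualization")
}

#' @export
print.residualization <- function(x, ...) {
  cat(sprintf("OLS residualization (n = %d, intercept = %.4g)\n",
              x$n_used, x$intercept))
  print(transform(x$coefficients, beta = signif(beta, 4),
                  t = round(t, 2), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Shift-and-log transform of residualized values
#'
#' Residuals are mean-zero, so they cannot be log-transformed directly;
#' the variable's original sample mean (or an explicit constant) is added
#' back before taking the natural log, keeping the scale interpretable and
#' the argument positive. Any non-positive shifted value is an error that
#' lists the offending positions — never a silent clip.
#'
#' @param x a [residualize()] result or a numeric vector of residuals.
#' @param recenter constant added before logging; defaults to the
#'   residualization's stored raw-value mean.
#' @return numeric vector `log(residual + recenter)` (monotone in the
#'   input).
#' @export
shift_log_transform <- function(x, recenter = NULL) {
  if (inherits(x, "residualization")) {
    recenter <- recenter %||% x$center
    x <- x$residuals
  }
  if (is.null(recenter))
    stop("'recenter' is required for a bare numeric vector")
  shifted <- x + recenter
  bad <- which(!is.na(shifted) & shifted <= 0)
  if (length(bad))
    stop("non-positive values after recentering at position(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  log(shifted)
}

#' One-sided interquartile-range outlier filter
#'
#' Excludes points strictly greater than `Q3 + k * IQR` (no lower-tail
#' exclusion), with quartiles computed once on the input by linear
#' interpolation between order statistics (`stats::quantile` type 7, the
#' method configurable via `type`). A constant vector has zero IQR and
#' nothing is excluded. Values exactly on the threshold are kept.
#'
#' @param values numeric vector with at least 4 non-missing values.
#' @param k IQR multiplier (default 3).
#' @param type quantile method passed to [stats::quantile()].
#' @return list with `keep` (logical mask, `NA` values kept), `excluded`
#'   (integer positions), `q3`, `iqr`, `threshold`.
#' @export
iqr_upper_filter <- function(values, k = 3, type = 7) {
  if (k <= 0) stop("'k' must be positive")
  ok <- !is.na(values)
  if (sum(ok) < 4L) stop("need at least 4 non-missing values")
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = type,
                       names = FALSE)
  iqr <- q[2L] - q[1L]
  threshold <- q[2L] + k * iqr
  excl <- ok & values > threshold
  list(keep = !excl, excluded = which(excl), q3 = q[2L], iqr = iqr,
       threshold = threshold)
}

#' Preprocess a biomarker table for correlation / twin analysis
#'
#' Applies the fixed pipeline to each requested variable of a
#' subject-level table: CKD filter (once, table-level), OLS
#' residualization on the per-variable covariate list, shift-log
#' transform, and the one-sided IQR filter (excluded points are set to
#' `NA`). Every exclusion is counted and returned by cause; nothing is
#' dropped silently.
#'
#' Residualization and logging cannot literally happen in that order for
#' zero-mean residuals; by default the variable's sample mean is added back
#' before logging ([shift_log_transform()]). The alternative
#' `order = "log_first"` takes the natural log of the (strictly positive)
#' raw values before residualizing, which is numerically safer for
#' strongly right-skewed markers and leaves correlations of the processed
#' scores unchanged up to the monotone transform choice.
#'
#' @param records subject-level data frame.
#' @param variables named list: per variable, the character vector of
#'   covariate columns to residualize on.
#' @param egfr_threshold CKD exclusion threshold; set `NULL` to skip.
#' @param k IQR multiplier.
#' @param log_transform apply a log step at all (default TRUE).
#' @param order `"residualize_first"` (residualize, then shift-log) or
#'   `"log_first"` (log raw values, then residualize).
#' @return list with `data` (processed table: `<var>_adj` columns added),
#'   `log` (data frame of exclusion counts by variable and cause),
#'   `coefficients` (per-variable residualization reports), and
#'   `ckd_excluded` ids.
#' @export
preprocess_biomarkers <- function(records, variables,
                                  egfr_threshold = 30, k = 3,
                                  log_transform = TRUE,
                                  order = c("residualize_first",
                                            "log_first")) {
  order <- match.arg(order)
  ckd_excluded <- character(0)
  if (!is.null(egfr_threshold) && "egfr" %in% names(records)) {
    fl <- filter_ckd(records, egfr_threshold)
    ckd_excluded <- fl$excluded
    records <- fl$kept
  }
  logs <- list(); coefs <- list()
  for (v in names(variables)) {
    covs <- variables[[v]]
    miss_cov <- sum(!is.na(records[[v]]) &
                      !stats::complete.cases(
                        records[covs]))
    if (log_transform && order == "log_first") {
      raw <- records[[v]]
      bad <- which(!is.na(raw) & raw <= 0)
      if (length(bad))
        stop("non-positive '", v, "' values cannot be log-transformed ",
             "at position(s): ",
             paste(utils::head(bad, 10L), collapse = ", "))
      rz <- residualize(log(raw), records[covs])
      x <- rz$residuals
    } else {
      rz <- residualize(records[[v]], records[covs])
      x <- if (log_transform) shift_log_transform(rz) else rz$residuals
    }
    fl <- iqr_upper_filter(x, k = k)
    x[!fl$keep] <- NA_real_
    records[[paste0(v, "_adj")]] <- x
    logs[[v]] <- data.frame(variable = v, n_used = rz$n_used,
                            missing_covariates = miss_cov,
                            iqr_excluded = length(fl$excluded))
    coefs[[v]] <- rz$coefficients
  }
  list(data = records, log = do.call(rbind, logs),
       coefficients = coefs, ckd_excluded = ckd_excluded)
}
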