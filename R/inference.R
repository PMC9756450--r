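# Model comparison, fit indices and profile-likelihood intervals.

#' Likelihood-ratio test between nested FIML fits
#'
#' The naive chi-square reference distribution is used (no 50:50 boundary
#' mixture), the convention under which the published twin-model comparison
#' tables in this literature are computed; it is conservative for variance
#' components tested on their boundary.
#'
#' @param full,nested model fits on the same data; any objects carrying
#'   `m2ll` and `ep` (e.g. [twin_ace()], [twin_saturated()]) or plain lists
#'   with those fields. `nested$ep` must be smaller.
#' @param tol allowed negative slack in the -2LL difference before an
#'   optimizer-inconsistency error is raised.
#' @return list with `d_m2ll`, `d_df`, `p`.
#' @examples
#' lrt(list(m2ll = 100, ep = 4), list(m2ll = 103.841, ep = 3))
#' @export
lrt <- function(full, nested, tol = 1e-4) {
  if (nested$ep >= full$ep)
    stop("'nested' must have fewer estimated parameters than 'full'")
  d <- nested$m2ll - full$m2ll
  if (d < -tol)
    stop(sprintf(paste0("nested model fits better than the full model ",
                        "(d-2LL = %.6g): optimizer inconsistency"), d))
  d <- max(d, 0)
  ddf <- full$ep - nested$ep
  list(d_m2ll = d, d_df = ddf,
       p = stats::pchisq(d, df = ddf, lower.tail = FALSE))
}

#' Akaike information criterion from a -2 log-likelihood
#'
#' `AIC = -2LL + 2 * ep`. Accepts either a fit object carrying `m2ll` and
#' `ep` or the two numbers directly.
#'
#' @param fit a fit object, or the -2LL value.
#' @param ep parameter count when `fit` is a bare number.
#' @examples
#' aic_from_m2ll(4981.28, 8)  # 4997.28
#' @export
aic_from_m2ll <- function(fit, ep = NULL) {
  if (is.list(fit)) return(fit$m2ll + 2 * fit$ep)
  stopifnot_scalar(fit, "fit")
  fit + 2 * ep
}

#' Select the best-fitting model by AIC
#'
#' Lowest AIC wins; ties are broken toward the model with fewer estimated
#' parameters. The rationale records each sub-model's likelihood-ratio test
#' against the full model.
#'
#' @param fits named list of fits (each with `m2ll`, `ep`, `AIC` or
#'   computable AIC).
#' @param full the full model for the LRT column (defaults to the first).
#' @return list with `best` (name), `aic` (named vector) and `rationale`
#'   (data frame of LRTs vs the full model).
#' @export
select_best <- function(fits, full = NULL) {
  if (!length(fits)) stop("empty model list")
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$model %||% "model", "")
  full <- full %||% fits[[1L]]
  aics <- vapply(fits, aic_from_m2ll, numeric(1L))
  eps <- vapply(fits, function(f) f$ep, numeric(1L))
  ord <- order(aics, eps)
  rationale <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (f$ep >= full$ep)
      return(data.frame(model = nm, d_m2ll = NA_real_, d_df = NA_real_,
                        p = NA_real_, AIC = aics[[nm]]))
    tst <- lrt(full, f)
    data.frame(model = nm, d_m2ll = tst$d_m2ll, d_df = tst$d_df,
               p = tst$p, AIC = aics[[nm]])
  }))
  list(best = names(fits)[ord[1L]], aic = aics, rationale = rationale)
}

#' Implied phenotypic correlation of a bivariate twin model
#'
#' Reassembles the cross-trait phenotypic correlation from standardized
#' variance shares and factor correlations:
#' \deqn{r = \sqrt{a^2_1 a^2_2}\, r_g + \sqrt{c^2_1 c^2_2}\, r_c +
#'       \sqrt{e^2_1 e^2_2}\, r_e.}
#'
#' @param x a bivariate `twin_ace` fit, or a list with `shares` (3 x 2
#'   matrix, rows a2/c2/e2) and `rg`, `rc`, `re` (undefined ones may be NA).
#' @return the implied correlation (scalar).
#' @examples
#' implied_phenotypic_correlation(list(
#'   shares = rbind(a2 = c(0.54, 0.60), c2 = c(0, 0), e2 = c(0.46, 0.40)),
#'   rg = 0.46, rc = NA, re = 0.27))  # 0.3776
#' @export
implied_phenotypic_correlation <- function(x) {
  sh <- x$shares
  if (is.null(sh) || ncol(sh) != 2L)
    stop("a bivariate fit (two traits) is required")
  term <- function(row, r) {
    if (is.null(r) || is.na(r)) return(0)
    unname(sqrt(sh[row, 1L] * sh[row, 2L]) * r)
  }
  term("a2", x$rg) + term("c2", x$rc) + term("e2", x$re)
}

#' Model fit indices against saturated and independence baselines
#'
#' Computes the likelihood-ratio chi-square of a structured model against
#' the saturated model, with RMSEA and CFI:
#' \deqn{\chi^2 = -2LL_{model} + 2LL_{sat},\quad
#'   RMSEA = \sqrt{\max(0, \chi^2 - df)/(df\, n)},\quad
#'   CFI = 1 - \frac{\max(\chi^2_m - df_m, 0)}
#'                  {\max(\chi^2_i - df_i, \chi^2_m - df_m, 0)}.}
#' The baseline (independence) model frees means and variances but fixes
#' every covariance to zero. `n_units` is the number of families.
#'
#' @param model_fit,saturated_fit,independence_fit fits carrying `m2ll`,
#'   `ep`.
#' @param n_units sample-size unit for RMSEA (number of families).
#' @return list with `chi2`, `df`, `p`, `RMSEA`, `CFI`.
#' @export
fit_indices <- function(model_fit, saturated_fit, independence_fit,
                        n_units) {
  chi2_m <- model_fit$m2ll - saturated_fit$m2ll
  df_m <- saturated_fit$ep - model_fit$ep
  if (chi2_m < -1e-4)
    stop("model -2LL below the saturated model's: optimizer failure")
  chi2_m <- max(chi2_m, 0)
  chi2_i <- max(independence_fit$m2ll - saturated_fit$m2ll, 0)
  df_i <- saturated_fit$ep - independence_fit$ep
  rmsea <- if (df_m > 0) sqrt(max(0, chi2_m - df_m) / (df_m * n_units))
           else 0
  denom <- max(chi2_i - df_i, chi2_m - df_m, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi2_m - df_m, 0) / denom
  list(chi2 = chi2_m, df = df_m,
       p = stats::pchisq(chi2_m, df = max(df_m, 1), lower.tail = FALSE),
       RMSEA = rmsea, CFI = cfi)
}

# ---- profile-likelihood intervals --------------------------------------

# minimized -2LL with one quantity held fixed
ace_profile_m2ll <- function(fit, fixed) {
  layout <- ace_layout(length(fit$traits), fit$model, fixed = fixed)
  par0 <- fit$par[layout$names]
  obj <- ace_objective(fit$pdata, layout)
  opt <- tryCatch(multistart_optim(par0, obj, n_starts = 2L),
                  error = function(e) NULL)
  if (is.null(opt)) .PENALTY else opt$value
}

#' Profile-likelihood confidence interval for a twin-model quantity
#'
#' Finds the parameter values at which the profile -2LL (re-optimizing all
#' other parameters) rises by `qchisq(level, 1)` (3.841 for 95%) above its
#' minimum. Intervals are clipped at the quantity's natural bounds — \[0, 1\]
#' for standardized shares, \[-1, 1\] for factor correlations — and a bound
#' that cannot be bracketed inside the natural range is returned one-sided
#' with `clipped` flagged.
#'
#' @param fit a converged [twin_ace()] fit.
#' @param parameter one of `"h2.<trait>"` (alias `"a2.<trait>"`),
#'   `"c2.<trait>"`, `"e2.<trait>"`, `"rg"`, `"rc"`, `"re"`.
#' @param level confidence level.
#' @return list `lo`, `hi`, `estimate`, `clipped` (character, which bounds
#'   were clipped at the natural range).
#' @export
profile_ci <- function(fit, parameter, level = 0.95) {
  stopifnot(inherits(fit, "twin_ace"))
  crit <- stats::qchisq(level, df = 1L)
  target <- fit$m2ll + crit
  if (grepl("^(h2|a2|c2|e2)\\.", parameter)) {
    comp <- sub("\\..*$", "", parameter)
    comp <- c(h2 = "A", a2 = "A", c2 = "C", e2 = "E")[[comp]]
    trait <- sub("^[ace2h]+\\.", "", parameter)
    ti <- match(trait, fit$traits)
    if (is.na(ti)) stop("unknown trait '", trait, "'")
    est <- fit$shares[c(A = "a2", C = "c2", E = "e2")[[comp]], ti]
    pm2 <- function(v) ace_profile_m2ll(
      fit, list(type = "share", comp = comp, trait = ti, value = v))
    lo_nat <- 0; hi_nat <- 1 - 1e-6
  } else if (parameter %in% c("rg", "rc", "re")) {
    est <- fit[[parameter]]
    if (is.null(est) || is.na(est))
      stop("'", parameter, "' is not defined under the ", fit$model,
           " model")
    zn <- c(rg = "zg", rc = "zc", re = "ze")[[parameter]]
    pm2 <- function(v) ace_profile_m2ll(
      fit, list(type = "cor", which = zn, value = v))
    lo_nat <- -1 + 1e-9; hi_nat <- 1 - 1e-9
  } else stop("unknown parameter '", parameter, "'")
  f <- function(v) pm2(v) - target
  clipped <- character(0)
  bound <- function(side) {
    nat <- if (side == "lo") lo_nat else hi_nat
    atb <- f(nat)
    if (is.na(atb) || atb < 0) {
      clipped <<- c(clipped, side)
      return(nat)
    }
    interval <- sort(c(est, nat))
    stats::uniroot(f, interval = interval, tol = 1e-5,
                   extendInt = "no")$root
  }
  lo <- bound("lo"); hi <- bound("hi")
  list(lo = lo, hi = hi, estimate = est, clipped = clipped)
}

#' @rdname profile_ci
#' @param object,parm,... standard [stats::confint()] arguments; `parm`
#'   names quantities as in `parameter`.
#' @export
confint.twin_ace <- function(object, parm = NULL, level = 0.95, ...) {
  if (is.null(parm)) {
    parm <- paste0("h2.", object$traits)
    if (length(object$traits) == 2L)
      parm <- c(parm, intersect(c("rg", "rc", "re"),
                                names(coef(object))))
  }
  out <- t(vapply(parm, function(p)
    unlist(profile_ci(object, p, level = level)[c("lo", "hi")]),
    numeric(2L)))
  colnames(out) <- sprintf("%g %%", 100 * c((1 - level) / 2,
                                            1 - (1 - level) / 2))
  out
}
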