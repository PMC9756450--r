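# Univariate ACE-family and bivariate correlated-factors twin models,
# estimated by raw-data (full-information) maximum likelihood.
#
# Parameterization: unconstrained path coefficients a, c, e per trait
# (variance components are their squares, which enforces non-negativity)
# and factor correlations through atanh-scale parameters (which enforces
# the (-1, 1) bounds). Sign indeterminacy of the paths is immaterial since
# only squares are reported; correlation signs are identified because the
# cross-trait covariances use r * sqrt(A1 * A2) with non-negative square
# roots.

# ---- parameter layout --------------------------------------------------

ace_layout <- function(k, model, fixed = NULL) {
  model <- match.arg(model, c("ACE", "AE", "CE", "E"))
  has <- c(A = model %in% c("ACE", "AE"),
           C = model %in% c("ACE", "CE"),
           E = TRUE)
  nm <- paste0("mu", seq_len(k))
  for (comp in c("A", "C", "E"))
    if (has[[comp]]) nm <- c(nm, paste0(tolower(comp), seq_len(k)))
  if (k == 2L) {
    if (has[["A"]]) nm <- c(nm, "zg")
    if (has[["C"]]) nm <- c(nm, "zc")
    nm <- c(nm, "ze")
  }
  if (!is.null(fixed)) {
    drop_nm <- if (fixed$type == "cor") fixed$which
               else paste0(tolower(fixed$comp), fixed$trait)
    if (!drop_nm %in% nm)
      stop("cannot fix '", drop_nm, "': not a parameter of the ", model,
           " model", call. = FALSE)
    nm <- setdiff(nm, drop_nm)
  }
  list(k = k, model = model, has = has, names = nm, fixed = fixed)
}

# decode a free-parameter vector into means, raw components and correlations
ace_decode <- function(par, layout) {
  k <- layout$k
  g <- function(n) {
    i <- match(n, layout$names)
    ifelse(is.na(i), NA_real_, par[i])
  }
  mu <- g(paste0("mu", seq_len(k)))
  path <- function(comp) {
    if (!layout$has[[comp]]) return(rep(0, k))
    v <- g(paste0(tolower(comp), seq_len(k)))
    v[is.na(v)] <- 0  # placeholder for a fixed-share path, filled below
    v
  }
  a <- path("A"); cc <- path("C"); e <- path("E")
  A <- a^2; C <- cc^2; E <- e^2
  zcor <- function(n, present) {
    if (k == 1L || !present) return(0)
    v <- g(n)
    if (is.na(v)) return(NA_real_)  # fixed correlation, filled below
    tanh(v)
  }
  rg <- zcor("zg", layout$has[["A"]])
  rc <- zcor("zc", layout$has[["C"]])
  re <- zcor("ze", TRUE)
  fx <- layout$fixed
  if (!is.null(fx)) {
    if (fx$type == "cor") {
      if (fx$which == "zg") rg <- fx$value
      if (fx$which == "zc") rc <- fx$value
      if (fx$which == "ze") re <- fx$value
    } else {
      # fixed standardized share s of component `comp` for trait `trait`:
      # X_i = s / (1 - s) * (sum of the other components for that trait)
      i <- fx$trait; s <- fx$value
      other <- switch(fx$comp, A = C[i] + E[i], C = A[i] + E[i],
                      E = A[i] + C[i])
      val <- if (s >= 1) Inf else s / (1 - s) * other
      if (fx$comp == "A") A[i] <- val
      if (fx$comp == "C") C[i] <- val
      if (fx$comp == "E") E[i] <- val
    }
  }
  list(mu = mu, A = A, C = C, E = E, rg = rg, rc = rc, re = re)
}

# implied pair covariance without input validation (hot path)
ace_cov_quick <- function(p, ra) {
  k <- length(p$A)
  fac <- function(v, r) {
    if (k == 1L) return(matrix(v, 1L, 1L))
    off <- r * sqrt(v[1L] * v[2L])
    matrix(c(v[1L], off, off, v[2L]), 2L, 2L)
  }
  kronecker(matrix(c(1, ra, ra, 1), 2L), fac(p$A, p$rg)) +
    kronecker(matrix(1, 2L, 2L), fac(p$C, p$rc)) +
    kronecker(diag(2L), fac(p$E, p$re))
}

ace_objective <- function(pdata, layout) {
  k <- layout$k
  function(par) {
    p <- ace_decode(par, layout)
    if (!all(is.finite(c(p$mu, p$A, p$C, p$E, p$rg, p$rc, p$re))))
      return(.PENALTY)
    mu2 <- rep(p$mu, 2L)
    tot <- 0
    for (z in c("MZ", "DZ")) {
      sg <- ace_cov_quick(p, ra = if (z == "MZ") 1 else 0.5)
      v <- fiml_m2ll_stats(pdata[[z]]$stats, mu2, sg, penalty = .PENALTY)
      if (v >= .PENALTY) return(.PENALTY)
      tot <- tot + v
    }
    tot
  }
}

# ---- moment-based starting values (Falconer) ---------------------------

ace_start <- function(pairs, traits, layout) {
  k <- layout$k
  mu0 <- a0 <- c0 <- e0 <- numeric(k)
  v0 <- numeric(k)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  for (i in seq_len(k)) {
    c1 <- paste0(traits[i], "_1"); c2 <- paste0(traits[i], "_2")
    all_v <- c(pairs[[c1]], pairs[[c2]])
    mu0[i] <- mean(all_v, na.rm = TRUE)
    v0[i] <- stats::var(all_v, na.rm = TRUE)
    rz <- function(z) {
      d <- pairs[pairs$zygosity == z, c(c1, c2)]
      d <- d[stats::complete.cases(d), , drop = FALSE]
      if (nrow(d) < 4L) return(NA_real_)
      stats::cor(d[[1L]], d[[2L]])
    }
    rmz <- rz("MZ"); rdz <- rz("DZ")
    if (is.na(rmz)) rmz <- 0.5
    if (is.na(rdz)) rdz <- 0.25
    a2 <- clamp(2 * (rmz - rdz), 0.01, 0.9)
    c2 <- clamp(2 * rdz - rmz, 0.01, 0.9)
    if (!layout$has[["C"]]) { a2 <- clamp(rmz, 0.05, 0.9); c2 <- 0 }
    if (!layout$has[["A"]]) { c2 <- clamp(rmz, 0.05, 0.9); a2 <- 0 }
    e2 <- max(1 - a2 - c2, 0.05)
    s <- a2 + c2 + e2
    a0[i] <- sqrt(a2 / s * v0[i])
    c0[i] <- sqrt(c2 / s * v0[i])
    e0[i] <- sqrt(e2 / s * v0[i])
  }
  par <- stats::setNames(rep(0.3, length(layout$names)), layout$names)
  for (i in seq_len(k)) {
    par[paste0("mu", i)] <- mu0[i]
    if (paste0("a", i) %in% layout$names) par[paste0("a", i)] <- a0[i]
    if (paste0("c", i) %in% layout$names) par[paste0("c", i)] <- c0[i]
    if (paste0("e", i) %in% layout$names) par[paste0("e", i)] <- e0[i]
  }
  if (k == 2L) {
    d <- pairs[, c(paste0(traits[1L], "_1"), paste0(traits[2L], "_1"))]
    d <- d[stats::complete.cases(d), , drop = FALSE]
    rxy <- if (nrow(d) >= 4L) clamp(stats::cor(d[[1L]], d[[2L]]), -0.9, 0.9)
           else 0.2
    for (zn in intersect(c("zg", "zc", "ze"), layout$names))
      par[zn] <- atanh(rxy)
  }
  par
}

# ---- the fitting function ----------------------------------------------

#' Fit a biometrical twin model by full-information maximum likelihood
#'
#' Decomposes the phenotypic variance of one trait (or the variances and
#' cross-trait covariance of two traits) measured on monozygotic and
#' dizygotic twin pairs into additive-genetic (A), common-environment (C)
#' and unique-environment (E) components, using the raw-data FIML
#' likelihood so that incomplete pairs and unpaired singletons contribute
#' their observed values. For two traits the bivariate "correlated factors"
#' model is fitted: each trait has its own A/C/E factors and the cross-trait
#' structure is carried by factor correlations `rg`, `rc`, `re`.
#'
#' The means model is a single grand mean per trait (mean and variance
#' homogeneity across twin order and zygosity is assumed; test it first
#' with [homogeneity_sequence()]). Sub-models drop components by fixing
#' them to zero: `"AE"` drops C, `"CE"` drops A, `"E"` drops both.
#'
#' @param pairs pair table: one row per family with columns `zygosity`
#'   (`"MZ"`/`"DZ"`) and `<trait>_1`, `<trait>_2` per trait; `NA` marks
#'   missing values, singletons have one twin's columns all `NA`.
#' @param traits character vector of 1 or 2 trait names.
#' @param model `"ACE"`, `"AE"`, `"CE"` or `"E"`.
#' @param start optional named start vector (advanced use).
#' @param n_starts number of deterministic multi-start jitters.
#' @return an object of class `twin_ace` with components `m2ll`, `ep`, `df`
#'   (observed data values minus `ep`), `AIC`, raw components `A`, `C`, `E`,
#'   standardized `shares` (rows a2/c2/e2, columns traits, summing to 1),
#'   `h2`, and for two traits `rg`, `rc`, `re` (those defined under the
#'   model) plus the implied phenotypic correlation.
#' @seealso [twin_ace_models()] to fit the whole ACE/AE/CE/E family,
#'   [confint.twin_ace()] for profile-likelihood intervals.
#' @examples
#' coh <- simulate_twin_cohort(twin_design(100, 100, 0),
#'                             twin_acemodel_std(h2 = 0.6), seed = 1)
#' fit <- twin_ace(coh$pairs, "trait1", model = "AE")
#' fit$h2
#' @export
twin_ace <- function(pairs, traits, model = c("ACE", "AE", "CE", "E"),
                     start = NULL, n_starts = 5L) {
  model <- match.arg(model)
  k <- length(traits)
  if (!k %in% 1:2) stop("'traits' must name 1 or 2 traits")
  pdata <- pair_fiml_data(pairs, traits)
  layout <- ace_layout(k, model)
  par0 <- ace_start(pairs, traits, layout)
  if (!is.null(start)) par0[names(start)] <- start
  obj <- ace_objective(pdata, layout)
  opt <- multistart_optim(par0, obj, n_starts = n_starts)
  p <- ace_decode(opt$par, layout)
  tot <- p$A + p$C + p$E
  shares <- rbind(a2 = p$A / tot, c2 = p$C / tot, e2 = p$E / tot)
  colnames(shares) <- traits
  ep <- length(layout$names)
  out <- list(
    model = model, traits = traits,
    par = stats::setNames(opt$par, layout$names),
    layout = layout, pdata = pdata,
    m2ll = opt$value, ep = ep,
    n_obs = pdata$n_obs, n_families = pdata$n_families,
    df = pdata$n_obs - ep,
    AIC = opt$value + 2 * ep,
    mu = stats::setNames(p$mu, traits),
    A = stats::setNames(p$A, traits),
    C = stats::setNames(p$C, traits),
    E = stats::setNames(p$E, traits),
    shares = shares,
    h2 = shares["a2", ],
    boundary = (layout$has[["A"]] && any(shares["a2", ] < 1e-4)) ||
               (layout$has[["C"]] && any(shares["c2", ] < 1e-4)),
    convergence = list(code = opt$convergence, restarts = opt$restarts,
                       start_used = opt$start_used),
    call = match.call()
  )
  if (k == 2L) {
    out$rg <- if (layout$has[["A"]]) p$rg else NA_real_
    out$rc <- if (layout$has[["C"]]) p$rc else NA_real_
    out$re <- p$re
    out$implied_r <- implied_phenotypic_correlation(out)
  }
  class(out) <- "twin_ace"
  out
}

#' Fit the full ACE/AE/CE/E model family on one data set
#'
#' Fits the requested sub-models, enforces nested-likelihood monotonicity
#' (a sub-model can never beat the model it is nested in; when an optimizer
#' run violates this the fuller model is refitted from the sub-model's
#' solution), and returns the fits plus a comparison table against the full
#' ACE model.
#'
#' @inheritParams twin_ace
#' @param models character vector of models to fit.
#' @return list with `fits` (named list of `twin_ace` objects), `table`
#'   (model, ep, -2LL, df, dLL/ddf/p versus ACE, AIC) and `best`
#'   (lowest AIC, ties broken toward fewer parameters).
#' @export
twin_ace_models <- function(pairs, traits,
                            models = c("ACE", "AE", "CE", "E")) {
  models <- match.arg(models, c("ACE", "AE", "CE", "E"),
                      several.ok = TRUE)
  fits <- lapply(models, function(m) twin_ace(pairs, traits, model = m))
  names(fits) <- models
  # monotonicity repair: ACE must fit at least as well as AE/CE, which must
  # fit at least as well as E
  embed <- function(par_from, fit_to) {
    st <- fit_to$par
    shared <- intersect(names(par_from), names(st))
    st[shared] <- par_from[shared]
    # jitter paths of extra components off exactly zero
    extra <- setdiff(names(st), shared)
    st[extra] <- ifelse(grepl("^z", extra), 0, 0.05)
    st
  }
  repair <- function(full, nested) {
    if (!(full %in% models && nested %in% models)) return(invisible())
    if (fits[[nested]]$m2ll < fits[[full]]$m2ll - 1e-4) {
      st <- embed(fits[[nested]]$par, fits[[full]])
      refit <- twin_ace(pairs, traits, model = full, start = st)
      if (refit$m2ll < fits[[full]]$m2ll) fits[[full]] <<- refit
    }
    invisible()
  }
  for (nst in c("AE", "CE", "E")) repair("ACE", nst)
  repair("AE", "E"); repair("CE", "E")
  full <- fits[[models[1L]]]
  tab <- do.call(rbind, lapply(fits, function(f) {
    cmp <- if (identical(f$model, full$model))
      c(NA_real_, NA_real_, NA_real_)
    else unlist(lrt(full, f))
    data.frame(model = f$model, ep = f$ep, m2ll = f$m2ll, df = f$df,
               d_m2ll = cmp[1L], d_df = cmp[2L], p = cmp[3L],
               AIC = f$AIC, row.names = NULL)
  }))
  sel <- select_best(fits, full = full)
  list(fits = fits, table = tab, best = sel$best, selection = sel)
}

# ---- S3 methods --------------------------------------------------------

#' @export
print.twin_ace <- function(x, ...) {
  cat(sprintf("Twin %s model (%s), FIML\n", x$model,
              paste(x$traits, collapse = " + ")))
  cat(sprintf("  families: %d   observed values: %d\n",
              x$n_families, x$n_obs))
  cat(sprintf("  -2LL = %.2f   ep = %d   df = %d   AIC = %.2f\n",
              x$m2ll, x$ep, x$df, x$AIC))
  cat("  standardized components:\n")
  print(round(x$shares, 3))
  if (length(x$traits) == 2L) {
    cat(sprintf("  rg = %s  rc = %s  re = %.3f   implied r = %.3f\n",
                if (is.na(x$rg)) "--" else sprintf("%.3f", x$rg),
                if (is.na(x$rc)) "--" else sprintf("%.3f", x$rc),
                x$re, x$implied_r))
  }
  invisible(x)
}

#' @export
coef.twin_ace <- function(object, ...) {
  out <- c(object$mu,
           stats::setNames(as.vector(object$shares),
                           paste(rep(rownames(object$shares),
                                     ncol(object$shares)),
                                 rep(object$traits,
                                     each = nrow(object$shares)),
                                 sep = ".")))
  if (length(object$traits) == 2L)
    out <- c(out, rg = object$rg, rc = object$rc, re = object$re)
  out[!is.na(out)]
}

#' @export
logLik.twin_ace <- function(object, ...) {
  structure(-object$m2ll / 2, df = object$ep, nobs = object$n_families,
            class = "logLik")
}

#' @export
summary.twin_ace <- function(object, ci = FALSE, level = 0.95, ...) {
  s <- list(fit = object)
  if (ci) {
    qs <- paste0("h2.", object$traits)
    if (length(object$traits) == 2L)
      qs <- c(qs, intersect(c("rg", "rc", "re"), names(coef(object))))
    s$ci <- t(vapply(qs, function(q)
      unlist(profile_ci(object, q, level = level)[c("lo", "hi")]),
      numeric(2L)))
  }
  class(s) <- "summary.twin_ace"
  s
}

#' @export
print.summary.twin_ace <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$ci)) {
    cat("  profile 95% CIs:\n")
    print(round(x$ci, 3))
  }
  invisible(x)
}

#' Likelihood-ratio comparison of nested twin models
#'
#' @param object the fuller model (more parameters).
#' @param ... one or more nested `twin_ace` fits on the same data.
#' @export
anova.twin_ace <- function(object, ...) {
  others <- list(...)
  rows <- lapply(others, function(n) as.data.frame(lrt(object, n)))
  cbind(model = vapply(others, function(n) n$model, ""),
        do.call(rbind, rows))
}

#' Simulate a twin cohort from a fitted twin model
#'
#' Draws new pair tables from the fitted variance components (parametric
#' bootstrap), using the fitted design's family counts.
#'
#' @param object a `twin_ace` fit.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param design optional [twin_design()]; defaults to the fitted data's
#'   MZ/DZ family counts with no singletons.
#' @param ... unused.
#' @export
simulate.twin_ace <- function(object, nsim = 1, seed = NULL, design = NULL,
                              ...) {
  if (is.null(seed)) seed <- 1L
  if (is.null(design))
    design <- twin_design(n_mz_pairs = object$pdata$MZ$n_families,
                          n_dz_pairs = object$pdata$DZ$n_families,
                          n_singletons = 0L)
  gm <- twin_acemodel(traits = object$traits, A = object$A, C = object$C,
                      E = object$E,
                      rg = if (is.null(object$rg) || is.na(object$rg)) 0
                           else object$rg,
                      rc = if (is.null(object$rc) || is.na(object$rc)) 0
                           else object$rc,
                      re = if (is.null(object$re) || is.na(object$re)) 0
                           else object$re,
                      means = object$mu, covariates = list(),
                      missing = stats::setNames(
                        rep(0, length(object$traits)), object$traits),
                      observed = "identity")
  out <- lapply(seq_len(nsim), function(i)
    simulate_twin_cohort(design, gm, seed = seed + i - 1L)$pairs)
  if (nsim == 1L) out[[1L]] else out
}
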