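# Saturated and independence models for twin-pair data, and the mean /
# variance homogeneity test sequence they support.

SAT_LEVELS <- c("saturated", "mean_within", "mean_across",
                "var_within", "var_across")

sat_layout_uni <- function(level) {
  level <- match.arg(level, SAT_LEVELS)
  li <- match(level, SAT_LEVELS)
  mu_nm <- if (li >= 3L) "mu"
           else if (li >= 2L) c("mu.MZ", "mu.DZ")
           else c("mu.MZ.1", "mu.MZ.2", "mu.DZ.1", "mu.DZ.2")
  lv_nm <- if (li >= 5L) "lv"
           else if (li >= 4L) c("lv.MZ", "lv.DZ")
           else c("lv.MZ.1", "lv.MZ.2", "lv.DZ.1", "lv.DZ.2")
  list(level = level, names = c(mu_nm, lv_nm, "z.MZ", "z.DZ"),
       mu_nm = mu_nm, lv_nm = lv_nm)
}

sat_moments_uni <- function(pairs, trait) {
  c1 <- paste0(trait, "_1"); c2 <- paste0(trait, "_2")
  out <- list()
  for (z in c("MZ", "DZ")) {
    d <- pairs[pairs$zygosity == z, c(c1, c2)]
    cc <- d[stats::complete.cases(d), , drop = FALSE]
    r <- if (nrow(cc) >= 4L) stats::cor(cc[[1L]], cc[[2L]]) else 0.3
    out[[z]] <- list(
      m = c(mean(d[[1L]], na.rm = TRUE), mean(d[[2L]], na.rm = TRUE)),
      v = c(stats::var(d[[1L]], na.rm = TRUE),
            stats::var(d[[2L]], na.rm = TRUE)),
      r = max(min(r, 0.95), -0.95))
  }
  out
}

sat_decode_uni <- function(par, layout) {
  g <- function(n) par[match(n, layout$names)]
  li <- match(layout$level, SAT_LEVELS)
  mu <- function(z) {
    if (li >= 3L) rep(g("mu"), 2L)
    else if (li >= 2L) rep(g(paste0("mu.", z)), 2L)
    else c(g(paste0("mu.", z, ".1")), g(paste0("mu.", z, ".2")))
  }
  vv <- function(z) {
    if (li >= 5L) rep(exp(g("lv")), 2L)
    else if (li >= 4L) rep(exp(g(paste0("lv.", z))), 2L)
    else exp(c(g(paste0("lv.", z, ".1")), g(paste0("lv.", z, ".2"))))
  }
  lapply(stats::setNames(c("MZ", "DZ"), c("MZ", "DZ")), function(z) {
    v <- vv(z); r <- tanh(g(paste0("z.", z)))
    sg <- matrix(c(v[1L], r * sqrt(v[1L] * v[2L]),
                   r * sqrt(v[1L] * v[2L]), v[2L]), 2L)
    list(mu = mu(z), sigma = sg, r = r)
  })
}

#' Saturated twin-pair model with cumulative homogeneity constraints
#'
#' Fits, by FIML, the model that frees every mean, variance and cross-twin
#' covariance of one trait separately by zygosity and twin order
#' (`"saturated"`, 10 parameters), or the same model under cumulative
#' equality constraints: means equal within zygosity (8), means equal
#' across zygosity (7), variances additionally equal within zygosity (5),
#' variances equal across zygosity (4). The per-zygosity cross-twin
#' covariances are always free.
#'
#' For two traits only the unconstrained saturated model is available
#' (per-zygosity 4 means + free 4x4 covariance, 28 parameters), the
#' baseline for [fit_indices()] on bivariate models.
#'
#' @inheritParams twin_ace
#' @param constraints one of `"saturated"`, `"mean_within"`,
#'   `"mean_across"`, `"var_within"`, `"var_across"` (cumulative).
#' @return object of class `twin_sat` with `m2ll`, `ep`, `df`, `AIC` and
#'   decoded per-zygosity moments.
#' @export
twin_saturated <- function(pairs, traits, constraints = "saturated",
                           n_starts = 3L) {
  k <- length(traits)
  pdata <- pair_fiml_data(pairs, traits)
  if (k == 1L) {
    layout <- sat_layout_uni(constraints)
    mom <- sat_moments_uni(pairs, traits)
    par0 <- stats::setNames(numeric(length(layout$names)), layout$names)
    pool_m <- mean(c(mom$MZ$m, mom$DZ$m))
    pool_v <- mean(c(mom$MZ$v, mom$DZ$v))
    for (nm in layout$names) {
      par0[nm] <- switch(substr(nm, 1L, 2L),
        "mu" = if (nm == "mu") pool_m
               else if (nm %in% c("mu.MZ", "mu.DZ"))
                 mean(mom[[substr(nm, 4L, 5L)]]$m)
               else mom[[substr(nm, 4L, 5L)]]$m[
                 as.integer(substr(nm, 7L, 7L))],
        "lv" = log(if (nm == "lv") pool_v
               else if (nm %in% c("lv.MZ", "lv.DZ"))
                 mean(mom[[substr(nm, 4L, 5L)]]$v)
               else mom[[substr(nm, 4L, 5L)]]$v[
                 as.integer(substr(nm, 7L, 7L))]),
        "z." = atanh(mom[[substr(nm, 3L, 4L)]]$r))
    }
    obj <- function(par) {
      dec <- sat_decode_uni(par, layout)
      tot <- 0
      for (z in c("MZ", "DZ")) {
        v <- fiml_m2ll_stats(pdata[[z]]$stats, dec[[z]]$mu,
                             dec[[z]]$sigma, penalty = .PENALTY)
        if (v >= .PENALTY) return(.PENALTY)
        tot <- tot + v
      }
      tot
    }
    opt <- multistart_optim(par0, obj, n_starts = n_starts)
    dec <- sat_decode_uni(opt$par, layout)
  } else if (k == 2L) {
    if (!identical(constraints, "saturated"))
      stop("homogeneity constraints are implemented for one trait")
    # per zygosity: 4 means + lower Cholesky of the 4x4 covariance
    tri <- lower.tri(diag(4L), diag = TRUE)
    layout <- list(level = "saturated",
                   names = as.vector(outer(
                     c(paste0("mu", 1:4), paste0("L", which(tri))),
                     c("MZ", "DZ"), paste, sep = ".")))
    par0 <- stats::setNames(numeric(28L), layout$names)
    cols <- pair_matrix_columns(traits)
    for (z in c("MZ", "DZ")) {
      d <- pairs[pairs$zygosity == z, cols]
      m <- colMeans(d, na.rm = TRUE)
      S <- stats::cov(d, use = "pairwise.complete.obs")
      S[is.na(S)] <- 0
      S <- S + diag(1e-6 * mean(diag(S)), 4L)
      ch <- tryCatch(t(chol(S)), error = function(e)
        diag(sqrt(diag(S))))
      L <- ch; diag(L) <- log(diag(L))
      par0[paste0("mu", 1:4, ".", z)] <- m
      par0[paste0("L", which(tri), ".", z)] <- L[tri]
    }
    decode_biv <- function(par) {
      lapply(stats::setNames(c("MZ", "DZ"), c("MZ", "DZ")), function(z) {
        mu <- par[paste0("mu", 1:4, ".", z)]
        L <- matrix(0, 4L, 4L)
        L[tri] <- par[paste0("L", which(tri), ".", z)]
        diag(L) <- exp(diag(L))
        list(mu = as.numeric(mu), sigma = L %*% t(L))
      })
    }
    obj <- function(par) {
      dec <- decode_biv(par)
      tot <- 0
      for (z in c("MZ", "DZ")) {
        v <- fiml_m2ll_stats(pdata[[z]]$stats, dec[[z]]$mu,
                             dec[[z]]$sigma, penalty = .PENALTY)
        if (v >= .PENALTY) return(.PENALTY)
        tot <- tot + v
      }
      tot
    }
    opt <- multistart_optim(par0, obj, n_starts = n_starts)
    dec <- decode_biv(opt$par)
  } else stop("'traits' must name 1 or 2 traits")
  ep <- length(layout$names)
  structure(list(model = paste0("saturated/", constraints),
                 level = constraints, traits = traits,
                 m2ll = opt$value, ep = ep, n_obs = pdata$n_obs,
                 n_families = pdata$n_families,
                 df = pdata$n_obs - ep, AIC = opt$value + 2 * ep,
                 moments = dec,
                 convergence = list(code = opt$convergence,
                                    start_used = opt$start_used)),
            class = "twin_sat")
}

#' @export
print.twin_sat <- function(x, ...) {
  cat(sprintf("Saturated twin model (%s), constraints: %s\n",
              paste(x$traits, collapse = " + "), x$level))
  cat(sprintf("  -2LL = %.2f  ep = %d  df = %d  AIC = %.2f\n",
              x$m2ll, x$ep, x$df, x$AIC))
  invisible(x)
}

#' Independence model (zero covariances) for twin-pair data
#'
#' Baseline for [fit_indices()]: every variable (trait x twin order x
#' zygosity) keeps a free mean and variance but all covariances are fixed
#' to zero, so the FIML likelihood factorizes per column and the MLE is
#' closed form (observed-value means and 1/n variances).
#'
#' @inheritParams twin_ace
#' @return a `twin_sat`-like list with `m2ll`, `ep`, `df`.
#' @export
twin_independence <- function(pairs, traits) {
  pdata <- pair_fiml_data(pairs, traits)
  m2ll <- 0
  ep <- 0L
  for (z in c("MZ", "DZ")) {
    y <- pdata[[z]]$y
    for (j in seq_len(ncol(y))) {
      x <- y[, j]; x <- x[!is.na(x)]
      n <- length(x)
      if (n == 0L) next
      vhat <- sum((x - mean(x))^2) / n
      m2ll <- m2ll + n * (log(2 * pi) + log(vhat) + 1)
      ep <- ep + 2L
    }
  }
  structure(list(model = "independence", traits = traits, m2ll = m2ll,
                 ep = ep, n_obs = pdata$n_obs,
                 n_families = pdata$n_families, df = pdata$n_obs - ep,
                 AIC = m2ll + 2 * ep),
            class = "twin_sat")
}

#' Mean and variance homogeneity test sequence
#'
#' Fits the saturated model and its four cumulative constrained versions
#' (means equal within zygosity, means equal across zygosity, variances
#' equal within zygosity, variances equal across zygosity; estimated
#' parameter counts 10, 8, 7, 5, 4) and compares each constrained model to
#' the saturated model by likelihood-ratio chi-square (changes in df 2, 3,
#' 5, 6). The verdict per step uses a Bonferroni-corrected threshold.
#'
#' @inheritParams twin_ace
#' @param trait single trait name.
#' @param alpha corrected significance threshold (default 0.01, i.e. 0.05
#'   Bonferroni-corrected over the homogeneity comparisons).
#' @return object of class `twin_homogeneity`: `table` (model, ep, -2LL,
#'   df, AIC, d-2LL, ddf, p, homogeneous) and the underlying `fits`.
#' @export
homogeneity_sequence <- function(pairs, trait, alpha = 0.01) {
  stopifnot(length(trait) == 1L)
  fits <- lapply(SAT_LEVELS, function(lv)
    twin_saturated(pairs, trait, constraints = lv))
  names(fits) <- SAT_LEVELS
  sat <- fits[[1L]]
  # monotonicity repair: each added constraint cannot reduce -2LL
  for (i in 2:5) if (fits[[i]]$m2ll < fits[[i - 1L]]$m2ll - 1e-4)
    fits[[i]] <- twin_saturated(pairs, trait,
                                constraints = SAT_LEVELS[i],
                                n_starts = 6L)
  tab <- do.call(rbind, lapply(SAT_LEVELS, function(lv) {
    f <- fits[[lv]]
    if (lv == "saturated") {
      data.frame(model = lv, ep = f$ep, m2ll = f$m2ll, df = f$df,
                 AIC = f$AIC, d_m2ll = NA_real_, d_df = NA_real_,
                 p = NA_real_, homogeneous = NA)
    } else {
      tst <- lrt(sat, f)
      data.frame(model = lv, ep = f$ep, m2ll = f$m2ll, df = f$df,
                 AIC = f$AIC, d_m2ll = tst$d_m2ll, d_df = tst$d_df,
                 p = tst$p, homogeneous = tst$p >= alpha)
    }
  }))
  structure(list(trait = trait, alpha = alpha, table = tab, fits = fits),
            class = "twin_homogeneity")
}

#' @export
print.twin_homogeneity <- function(x, ...) {
  cat(sprintf("Mean/variance homogeneity tests for '%s' (threshold p = %g)\n",
              x$trait, x$alpha))
  print(transform(x$table, m2ll = round(m2ll, 2), AIC = round(AIC, 2),
                  d_m2ll = round(d_m2ll, 2), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Maximum-likelihood twin-pair correlations by zygosity
#'
#' Estimates, separately for MZ and DZ pairs, the cross-twin correlation of
#' one trait under the constraint that mean and variance are equal for both
#' members of a pair, by FIML (incomplete pairs contribute their single
#' observed value). The confidence interval is profile likelihood; the p
#' value is the likelihood-ratio test of zero correlation.
#'
#' @inheritParams homogeneity_sequence
#' @param level confidence level.
#' @return data frame with one row per zygosity: `zygosity`, `n_pairs`
#'   (complete pairs), `r`, `lo`, `hi`, `p`.
#' @export
twin_correlations <- function(pairs, trait, level = 0.95) {
  stopifnot(length(trait) == 1L)
  c1 <- paste0(trait, "_1"); c2 <- paste0(trait, "_2")
  crit <- stats::qchisq(level, 1L)
  rows <- lapply(c("MZ", "DZ"), function(z) {
    d <- as.matrix(pairs[pairs$zygosity == z, c(c1, c2)])
    storage.mode(d) <- "double"
    ncomp <- sum(stats::complete.cases(d))
    if (ncomp < 4L)
      stop("need at least 4 complete ", z, " pairs")
    st <- fiml_pattern_stats(d)
    vals <- d[!is.na(d)]
    if (stats::var(vals) <= 0) stop("zero variance in '", trait, "'")
    m2 <- function(mu, lv, r) {
      v <- exp(lv)
      sg <- matrix(c(v, r * v, r * v, v), 2L)
      fiml_m2ll_stats(st, c(mu, mu), sg, penalty = .PENALTY)
    }
    fitr <- function(r) {  # profile over r
      stats::optim(c(mean(vals), log(stats::var(vals))),
                   function(p) m2(p[1L], p[2L], r),
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 2000L))$value
    }
    opt <- stats::optim(c(mean(vals), log(stats::var(vals)),
                          atanh(0.4)),
                        function(p) m2(p[1L], p[2L], tanh(p[3L])),
                        method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 1000L))
    r_hat <- tanh(opt$par[3L])
    target <- opt$value + crit
    cib <- function(side) {
      nat <- if (side == "lo") -1 + 1e-9 else 1 - 1e-9
      f <- function(r) fitr(r) - target
      if (f(nat) < 0) return(nat)
      stats::uniroot(f, sort(c(r_hat, nat)), tol = 1e-5)$root
    }
    p0 <- fitr(0) - opt$value
    data.frame(zygosity = z, n_pairs = ncomp, r = r_hat,
               lo = cib("lo"), hi = cib("hi"),
               p = stats::pchisq(max(p0, 0), 1L, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}
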