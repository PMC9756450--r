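#' Full-information maximum-likelihood objective for incomplete multivariate
#' normal data
#'
#' Computes minus twice the log-likelihood of a set of rows under a
#' multivariate normal model, where each row contributes the density of its
#' observed sub-vector only (the raw-data, or FIML, likelihood). Rows with no
#' observed values contribute zero.
#'
#' Internally rows are grouped by missingness pattern and evaluated from
#' pattern-level sufficient statistics (count, mean, scatter), which makes the
#' objective cheap to re-evaluate inside an optimizer for data sets with few
#' distinct patterns (e.g. complete twin-pair data).
#'
#' @param y numeric matrix (rows = observational units, columns = variables);
#'   `NA` marks a missing entry.
#' @param mu numeric mean vector, length `ncol(y)`.
#' @param sigma covariance matrix, `ncol(y)` square; must be positive definite
#'   on every observed subset of variables.
#' @return a single number, \eqn{-2\,\log L}.
#' @examples
#' mvn_m2ll(matrix(0), mu = 0, sigma = matrix(1))  # log(2*pi)
#' @export
mvn_m2ll <- function(y, mu, sigma) {
  y <- as.matrix(y)
  mu <- as.numeric(mu)
  sigma <- as.matrix(sigma)
  if (length(mu) != ncol(y) || any(dim(sigma) != ncol(y)))
    stop("dimensions of 'mu'/'sigma' do not match ncol(y)")
  st <- fiml_pattern_stats(y)
  fiml_m2ll_stats(st, mu, sigma, penalty = NULL)
}

# Group rows of y by missingness pattern and reduce each pattern to
# (observed column index, n, mean, scatter). Rows with nothing observed drop.
fiml_pattern_stats <- function(y) {
  y <- as.matrix(y)
  obs <- !is.na(y)
  keep <- rowSums(obs) > 0L
  y <- y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  if (nrow(y) == 0L) return(list())
  key <- apply(obs, 1L, function(o) paste(which(o), collapse = ","))
  out <- vector("list", length(unique(key)))
  i <- 0L
  for (k in unique(key)) {
    rows <- which(key == k)
    idx <- which(obs[rows[1L], ])
    x <- y[rows, idx, drop = FALSE]
    n <- nrow(x)
    m <- colMeans(x)
    xc <- sweep(x, 2L, m)
    i <- i + 1L
    out[[i]] <- list(idx = idx, n = n, mean = m, scatter = crossprod(xc))
  }
  out
}

# -2 log L from pattern sufficient statistics. With `penalty` non-NULL a
# non-positive-definite observed-subset covariance returns the penalty value
# (for use inside optimizers); otherwise it is a hard error.
fiml_m2ll_stats <- function(stats, mu, sigma, penalty = NULL) {
  tot <- 0
  for (st in stats) {
    k <- length(st$idx)
    sg <- sigma[st$idx, st$idx, drop = FALSE]
    ch <- tryCatch(chol(sg), error = function(e) NULL)
    if (is.null(ch) || any(!is.finite(ch)) ||
        any(diag(ch) < 1e-12)) {
      if (!is.null(penalty)) return(penalty)
      stop("covariance not positive definite on observed subset {",
           paste(st$idx, collapse = ","), "}", call. = FALSE)
    }
    logdet <- 2 * sum(log(diag(ch)))
    sinv <- chol2inv(ch)
    d <- st$mean - mu[st$idx]
    quad <- st$n * drop(crossprod(d, sinv %*% d)) + sum(sinv * st$scatter)
    tot <- tot + st$n * (k * log(2 * pi) + logdet) + quad
  }
  tot
}

# total number of observed (non-missing) data values; the df convention is
# df = observed values - estimated parameters
n_observed_values <- function(y) sum(!is.na(y))

# deterministic multi-start BFGS minimizer; starts[[1]] is the moment-based
# start, the rest deterministic jitters of it
multistart_optim <- function(par0, fn, n_starts = 5L, maxit = 1000L) {
  jitter_fac <- c(1, 0.8, 1.25, 0.5, 1.6)[seq_len(n_starts)]
  best <- NULL
  for (j in seq_along(jitter_fac)) {
    p0 <- par0 * jitter_fac[j] + (jitter_fac[j] - 1) * 0.1
    fit <- tryCatch(
      stats::optim(p0, fn, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # polish with Nelder-Mead if BFGS stalled on the penalty surface
    if (fit$value >= .PENALTY) {
      fit <- tryCatch(
        stats::optim(p0, fn, method = "Nelder-Mead",
                     control = list(maxit = 5000L, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit)) next
    }
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best$start_used <- j
    }
  }
  if (is.null(best) || best$value >= .PENALTY)
    stop("optimizer failed to find an admissible solution after ",
         n_starts, " starts", call. = FALSE)
  best$restarts <- n_starts
  best
}
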