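# Independent brute-force oracle for the FIML objective: per row, the
# multivariate-normal log density of the observed sub-vector, written from
# the density formula with solve()/det() (no Cholesky, no pattern
# grouping, shares no code with the package's likelihood path).
oracle_m2ll <- function(y, mu, sigma) {
  tot <- 0
  for (i in seq_len(nrow(y))) {
    obs <- which(!is.na(y[i, ]))
    if (!length(obs)) next
    x <- y[i, obs]
    m <- mu[obs]
    s <- sigma[obs, obs, drop = FALSE]
    logdens <- -0.5 * (length(obs) * log(2 * pi) +
                         log(det(s)) +
                         t(x - m) %*% solve(s) %*% (x - m))
    tot <- tot - 2 * as.numeric(logdens)
  }
  tot
}

# small deterministic pair table for smoke tests
toy_pairs <- function(n_mz = 60, n_dz = 60, h2 = c(0.54, 0.60),
                      rg = 0.46, re = 0.27, seed = 42) {
  k <- length(h2)
  gm <- if (k == 1L) twin_acemodel_std(h2 = h2)
        else twin_acemodel_std(h2 = h2, rg = rg, re = re)
  simulate_twin_cohort(twin_design(n_mz, n_dz, 0), gm, seed = seed)$pairs
}
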