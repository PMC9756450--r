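#' Expected twin-pair covariance under the ACE / correlated-factors model
#'
#' Builds the model-implied covariance matrix for one twin pair. For a single
#' trait this is the classical 2x2 ACE structure: total variance A + C + E on
#' the diagonal and cross-twin covariance A + C (monozygotic) or 0.5 A + C
#' (dizygotic), the additive-genetic cross-twin correlation being fixed at 1.0
#' for MZ and 0.5 for DZ pairs while the shared environment correlates 1.0 in
#' both. For two traits the correlated-factors extension adds factor
#' correlations `rg`, `rc`, `re` between the traits' A, C and E factors, so
#' that e.g. the within-person cross-trait covariance is
#' \eqn{r_g\sqrt{A_1A_2} + r_c\sqrt{C_1C_2} + r_e\sqrt{E_1E_2}} and the
#' cross-twin cross-trait covariance replaces the \eqn{r_g} term with
#' \eqn{0.5\,r_g\sqrt{A_1A_2}} in DZ pairs and drops the \eqn{r_e} term.
#'
#' @param A,C,E numeric vectors of raw variance components, one value per
#'   trait (length 1 or 2); all must be non-negative.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param rg,rc,re factor correlations in \[-1, 1\]; ignored for one trait.
#' @return covariance matrix of dimension `2 * length(A)`, variable order
#'   (twin1 trait1, twin1 trait2, twin2 trait1, twin2 trait2) — for one trait
#'   simply (twin1, twin2).
#' @examples
#' ace_expected_cov(A = 0.36, C = 0.16, E = 0.25, zygosity = "MZ")
#' @export
ace_expected_cov <- function(A, C, E, zygosity = c("MZ", "DZ"),
                             rg = 0, rc = 0, re = 0) {
  zygosity <- match.arg(zygosity)
  k <- length(A)
  if (length(C) != k || length(E) != k || !(k %in% 1:2))
    stop("'A', 'C', 'E' must have common length 1 or 2")
  if (any(A < 0) || any(C < 0) || any(E < 0))
    stop("raw variance components must be non-negative")
  if (any(abs(c(rg, rc, re)) > 1))
    stop("factor correlations must lie in [-1, 1]")
  ra <- if (zygosity == "MZ") 1 else 0.5
  fac <- function(v, r) {
    if (k == 1L) return(matrix(v, 1L, 1L))
    off <- r * sqrt(v[1L] * v[2L])
    matrix(c(v[1L], off, off, v[2L]), 2L, 2L)
  }
  SA <- fac(A, rg); SC <- fac(C, rc); SE <- fac(E, re)
  Rtwin <- matrix(c(1, ra, ra, 1), 2L, 2L)
  J2 <- matrix(1, 2L, 2L)
  kronecker(Rtwin, SA) + kronecker(J2, SC) + kronecker(diag(2L), SE)
}
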