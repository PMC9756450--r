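# Twin-pair table utilities.
#
# The package-wide "pair table" layout is one row per family:
#   family, zygosity ("MZ"/"DZ"), then <trait>_1 and <trait>_2 columns for
#   each trait (value for twin 1 / twin 2; NA = missing). Singletons are
#   families with one twin's entries entirely NA; they contribute marginal
#   likelihood terms in every FIML fit.

pair_columns <- function(traits) {
  as.vector(t(outer(traits, 1:2, function(tr, i) paste0(tr, "_", i))))
}

# column order used by the likelihood: twin1 traits..., twin2 traits...
# (matches ace_expected_cov)
pair_matrix_columns <- function(traits) {
  c(paste0(traits, "_1"), paste0(traits, "_2"))
}

check_pair_table <- function(pairs, traits) {
  if (!is.data.frame(pairs)) stop("'pairs' must be a data frame")
  if (!"zygosity" %in% names(pairs)) stop("'pairs' needs a 'zygosity' column")
  need <- pair_matrix_columns(traits)
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("missing trait columns: ", paste(miss, collapse = ", "))
  zyg <- as.character(pairs$zygosity)
  if (!all(zyg %in% c("MZ", "DZ")))
    stop("zygosity must be 'MZ' or 'DZ'")
  if (length(unique(zyg)) < 2L)
    stop("both MZ and DZ families are required: with a single zygosity ",
         "group the additive-genetic and shared-environment components ",
         "are not separately identifiable")
  invisible(TRUE)
}

# per-zygosity data matrices (twin1 traits, twin2 traits) and their FIML
# pattern statistics, computed once per data set
pair_fiml_data <- function(pairs, traits) {
  check_pair_table(pairs, traits)
  cols <- pair_matrix_columns(traits)
  out <- list()
  for (z in c("MZ", "DZ")) {
    y <- as.matrix(pairs[pairs$zygosity == z, cols, drop = FALSE])
    storage.mode(y) <- "double"
    out[[z]] <- list(y = y, stats = fiml_pattern_stats(y),
                     n_obs = n_observed_values(y),
                     n_families = sum(rowSums(!is.na(y)) > 0L))
  }
  out$n_obs <- out$MZ$n_obs + out$DZ$n_obs
  out$n_families <- out$MZ$n_families + out$DZ$n_families
  out$traits <- traits
  out
}

#' Randomly permute twin order within families
#'
#' Swaps the twin-1/twin-2 assignment of each family independently with
#' probability 1/2. Useful for checking that constrained model fits are
#' invariant to the (arbitrary) within-pair ordering.
#'
#' @param pairs pair table (see [twin_ace()]).
#' @param traits character vector of trait names.
#' @param seed integer seed.
#' @return the pair table with twin order permuted.
#' @export
permute_twin_order <- function(pairs, traits, seed = 1L) {
  set.seed(seed)
  swap <- stats::runif(nrow(pairs)) < 0.5
  for (tr in traits) {
    c1 <- paste0(tr, "_1"); c2 <- paste0(tr, "_2")
    tmp <- pairs[[c1]][swap]
    pairs[[c1]][swap] <- pairs[[c2]][swap]
    pairs[[c2]][swap] <- tmp
  }
  pairs
}
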