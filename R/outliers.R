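#' Inject upper-tail outliers into a vector
#'
#' Replaces a random subset of points by values placed `magnitude`
#' interquartile ranges above the third quartile of the clean input, so
#' that (for `magnitude > 3`) they fall strictly above the one-sided
#' `Q3 + 3 * IQR` exclusion threshold used by [iqr_upper_filter()]. Used
#' to exercise the outlier-exclusion stage with known ground truth.
#'
#' @param values numeric vector (may contain `NA`, which are never
#'   selected).
#' @param rate proportion of non-missing points to contaminate, in
#'   \[0, 1).
#' @param magnitude placement in multiples of the clean IQR above Q3; a
#'   warning is raised when `magnitude <= 3` since such points need not be
#'   excluded by a 3 x IQR filter.
#' @param seed integer seed; identical seeds select identical indices.
#' @return list with `values` (contaminated vector) and `index` (injected
#'   positions, integer, possibly empty).
#' @export
inject_outliers <- function(values, rate, magnitude = 10, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("'rate' must be in [0, 1)")
  if (magnitude <= 3)
    warning("magnitude <= 3: injected points may not exceed the ",
            "Q3 + 3*IQR exclusion threshold")
  ok <- which(!is.na(values))
  n_inj <- round(rate * length(ok))
  if (n_inj == 0L)
    return(list(values = values, index = integer(0)))
  set.seed(as.integer(seed))
  idx <- sort(sample(ok, n_inj))
  q <- stats::quantile(values[ok], c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  # strictly above Q3 + magnitude * IQR; a small positive offset keeps the
  # placement strict even when IQR is zero
  values[idx] <- q[2L] + magnitude * iqr +
    abs(stats::runif(n_inj, 0.01, 0.1)) * max(iqr, abs(q[2L]), 1)
  list(values = values, index = idx)
}
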