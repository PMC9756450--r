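# internal helpers shared across the package

.PENALTY <- 1e10

`%||%` <- function(a, b) if (is.null(a)) b else a

# most-frequent level first, so model.matrix uses it as the reference
relevel_by_frequency <- function(f) {
  f <- as.factor(f)
  tab <- table(f)
  factor(f, levels = names(sort(tab, decreasing = TRUE)))
}

# FNV-1a over a deparsed object; used to stamp reports with a config hash
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  invisible(x)
}
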