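# Internal helpers shared across modules.

# Deterministic fan-out of one integer seed into child seeds, kept < 2^31 so
# they remain valid R integer seeds. Used so that any single subject (or
# bootstrap stage) is reproducible from the cohort seed alone.
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647)
  as.integer((s * 48271 + as.numeric(index) * 1299721) %% 2147483629 + 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; a NULL seed
# uses (and advances) the ambient RNG.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(class, fmt, ...) {
  abort(sprintf(fmt, ...), class = c(class, "painbalance_error"))
}

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || anyNA(x)) {
    stopf("pb_validation_error", "`%s` must be numeric and non-missing.", name)
  }
  if (any(x < lo | x > hi)) {
    stopf("pb_validation_error", "`%s` must lie in [%s, %s].", name, lo, hi)
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stopf("pb_validation_error", "%s is missing column(s): %s.",
          what, paste(missing, collapse = ", "))
  }
  invisible(df)
}
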