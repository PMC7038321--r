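#' @importFrom rlang abort .data
#' @importFrom tibble tibble as_tibble
NULL

# error helpers: every user-facing failure carries a tremorforce error class
# so callers can condition on it
tf_abort <- function(msg, class) {
  abort(msg, class = c(class, "tremorforce_error"))
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok) {
    tf_abort(
      sprintf("`%s` must be a finite scalar in %s%s, %s]",
              name, if (strict_lower) "(" else "[", lower, upper),
      "tf_error_invalid_parameter"
    )
  }
  invisible(x)
}

# Derive a per-unit RNG seed from a base seed and an index; stays within
# the 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647)
}

fingers_one_hand <- c("thumb", "index", "middle", "ring", "little")

# sample standard deviation (n - 1 denominator) used throughout the studies
sd_sample <- function(x) stats::sd(x)
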