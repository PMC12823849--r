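# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower) stopf("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("`%s` must be >= %g", name, lower)
  if (strict_upper && x >= upper) stopf("`%s` must be < %g", name, upper)
  if (!strict_upper && x > upper) stopf("`%s` must be <= %g", name, upper)
  invisible(x)
}

assert_prob_vector <- function(p, name, tol = 1e-9) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stopf("`%s` must be a vector of non-negative probabilities", name)
  if (abs(sum(p) - 1) > tol)
    stopf("`%s` must sum to 1 (got %.12f)", name, sum(p))
  invisible(p)
}

# deterministic substream seeds so adding a field never perturbs earlier
# draws; Lehmer step keeps the result inside 32-bit integer range
substream_seed <- function(seed, stream_id) {
  as.integer((as.double(seed) * 48271 + stream_id) %% 2147483647)
}

logit <- function(p) log(p / (1 - p))
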