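# Internal numeric helpers shared across modules.

# log(exp(a) + exp(b)) without overflow, vectorized.
log_add_exp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  # -Inf + -Inf must stay -Inf, not NaN
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Run expr with a local RNG state seeded from `seed`; restores the caller's
# state afterwards so package functions never disturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a parent seed and a stream index, staying well
# inside the 32-bit integer range.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483629)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
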