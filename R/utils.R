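#' @keywords internal
"_PACKAGE"

# standard logistic
logistic <- function(x) 1 / (1 + exp(-x))

# Derive a child RNG seed from a master seed and a small offset, staying
# inside the 32-bit integer range R requires for set.seed().
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) + 7919 * as.numeric(offset)) %% 2147483587L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

assert_prob <- function(x, name) assert_number(x, name, 0, 1)
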