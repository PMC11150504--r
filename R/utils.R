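#' @keywords internal
"_PACKAGE"

## Condition helpers -------------------------------------------------------

# Input errors (bad files, bad arguments) are signalled with class
# "hm_input_error" so the CLI can map them to exit code 2; configuration
# errors of the generative models get "hm_config_error" (a subclass).
hm_input_error <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("hm_input_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

hm_config_error <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("hm_config_error", "hm_input_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# Scalar integer check used throughout validators.
is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x >= min
}

is_prob <- function(x) {
  is.numeric(x) & !is.na(x) & x >= 0 & x <= 1
}

# Run `expr` under a reproducible RNG state without touching the caller's
# stream. `seed = NULL` means: use (and advance) the global RNG.
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Uniform draw on {1, ..., m} vectorised over m (m may be a vector).
runif_int <- function(n, m) {
  1L + as.integer(floor(stats::runif(n) * m))
}
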