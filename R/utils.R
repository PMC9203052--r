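is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_rate <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s",
                  name, deparse(substitute(x))),
          class = "cfbrain_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is_scalar_number(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "cfbrain_config_error")
  }
  invisible(as.integer(x))
}

# Seeded evaluation that leaves the caller's RNG untouched; NULL seed uses
# (and advances) the ambient RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

`%theninform%` <- function(cond, msg) {
  if (cond) inform(msg)
  invisible(NULL)
}
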