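# internal helpers shared across modules

# run `code` under a fixed RNG seed without disturbing the caller's RNG state;
# seed = NULL leaves the RNG alone (caller-managed randomness)
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# derive independent sub-seeds (< 2^31) from one user seed
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

stop_config <- function(msg) abort(msg, class = "glc_config_error")
stop_numeric <- function(msg) abort(msg, class = "glc_numeric_error")

check_number <- function(x, name, lower = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x)))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (strict && x <= lower)
    abort(sprintf("`%s` must be > %g.", name, lower))
  if (!strict && x < lower)
    abort(sprintf("`%s` must be >= %g.", name, lower))
  invisible(x)
}

check_nonneg_vec <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    abort(sprintf("`%s` must be nonnegative.", name))
  invisible(x)
}

trapz_grid <- function(lower, upper, n = 25L) {
  if (!is.finite(lower) || !is.finite(upper) || lower <= 0 || upper <= lower)
    abort("inducer range must satisfy 0 < I_min < I_max.")
  exp(seq(log(lower), log(upper), length.out = n))
}
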