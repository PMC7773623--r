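# Round half away from zero (base round() rounds half to even); confusion
# matrix percentages are conventionally reported half-up to 1 decimal.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stable argmax/argmin with ties broken to the earliest index.
which_max_first <- function(x) which.max(x)
which_min_first <- function(x) which.min(x)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

# Draw from a seeded, isolated RNG stream without touching the caller's seed.
with_ct_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
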