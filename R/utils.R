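# Round half away from zero (arithmetic rounding). Report tables follow the
# convention of printing DALYs and person counts as integers rounded half-up,
# while all pipeline arithmetic keeps full precision.
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Stop unless `x` is a single non-missing numeric.
check_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (x < min) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, format(min), format(x)))
  }
  invisible(x)
}

near_sum <- function(x, target, tol = 1e-6) {
  abs(sum(x) - target) <= tol
}
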