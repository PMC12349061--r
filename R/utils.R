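# Internal helpers shared across modules.

# Deterministic 31-bit seed derivation: master seed + counter -> child seed.
# Multiplicative congruential step keeps everything exact in doubles
# (products stay < 2^53) and inside R's 32-bit integer seed range.
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1
  x <- (as.numeric(master) %% m) * 48271 + as.numeric(index) * 10007 + 1
  as.integer(x %% m)
}

stop_invalid <- function(msg, class, ...) {
  abort(msg, class = c(class, "copsplit_error"), ...)
}

check_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name),
                 "copsplit_invalid_parameter")
  }
  if (positive && x <= 0) {
    stop_invalid(sprintf("`%s` must be > 0", name),
                 "copsplit_invalid_parameter")
  }
  invisible(x)
}

# format doubles so that read back with as.numeric() is bit-identical
fmt_num <- function(x) sprintf("%.17g", x)
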