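# internal helpers shared across modules

# Round half away from zero (paper-style percentage rounding, e.g. 1/252 -> 0.4)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# stats::median that returns NA (no warning) on empty / all-NA input
median_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# derive independent sub-seeds from one master seed; keeps results < 2^31
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 10007) %% 2147483647
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
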