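# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

cf_stop <- function(...) stop(..., call. = FALSE)

# Derive a per-operation RNG stream from the user-facing seed. Streams are
# documented offsets so that independent operations never share a stream.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 1009 + stream * 9973) %% 2147483647)
}

# Run expr under a temporary RNG state seeded from `seed` (global RNG state
# is restored afterwards).
with_stream <- function(seed, stream, expr) {
  withr::with_seed(derive_seed(seed, stream), expr)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

# 0-based half-open interval midpoint with floor tie-break:
# mid = start + floor((end - start) / 2)
interval_midpoint <- function(start, end) start + (end - start) %/% 2L
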