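# internal helpers

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# full linear convolution, ascending coefficients; L is small so a tap loop
# over vectorized adds is exact and fast
conv_full <- function(x, f) {
  n <- length(x)
  L <- length(f)
  out <- numeric(n + L - 1L)
  for (j in seq_len(L)) {
    idx <- j:(j + n - 1L)
    out[idx] <- out[idx] + f[j] * x
  }
  out
}
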