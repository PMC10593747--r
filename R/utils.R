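# Internal helpers shared across modules.

hd_stop <- function(msg, class) {
  stop(structure(class = c(class, "hdtft_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample skewness (biased form is fine: only used to pick mean vs median).
hd_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - m)^3) / s^3
}

# Derive a stream-specific 31-bit seed from a base seed, so that independent
# random stages never share a stream.
hd_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream)) %% 2147483647L
}

hd_clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
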