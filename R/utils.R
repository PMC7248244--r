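# shared internal helpers

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# derive a 32-bit-safe child seed from a parent seed and a stream label
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * 131^(seq_along(utf8ToInt(as.character(stream))) %% 7))
  as.integer((abs(seed) * 69069 + h) %% 2147483647L)
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
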