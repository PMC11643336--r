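# internal helpers

# reflect-pad a series by n samples on each side (point reflection about the
# end values, so the padded series is continuous and slope-continuous)
pad_reflect <- function(x, n) {
  len <- length(x)
  n <- min(n, len - 1L)
  if (n < 1L) return(x)
  c(2 * x[1] - rev(x[2:(n + 1)]), x, 2 * x[len] - rev(x[(len - n):(len - 1)]))
}

unpad <- function(x, n, len) x[(n + 1):(n + len)]

# FNV-1a 32-bit hash of a character vector, returned as 8 hex digits.
# Used to fingerprint feature registries so tables built under different
# registries cannot be silently mixed.
fnv1a_hash <- function(strings) {
  bytes <- utf8ToInt(paste(strings, collapse = "\x1f"))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    # xor on values possibly >= 2^31: do it in two 16-bit halves
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    # 32-bit modular multiply (hi*2^16 + lo) * m without double overflow
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# derive a stream of child seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# run expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

stop_moveprof <- function(msg, class) {
  abort(msg, class = c(class, "moveprof_error"))
}
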