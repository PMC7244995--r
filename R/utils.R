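# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# broadcast a per-channel vector to a [H,W,C,N] array
bc_channel <- function(v, dims) {
  array(rep(rep(v, each = dims[1] * dims[2]), times = dims[4]), dim = dims)
}

# per-channel reduction of a [H,W,C,N] array: colSums/colMeans over (H,W,N)
channel_sum <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(1L, 2L, 4L, 3L))
  colSums(matrix(xp, d[1] * d[2] * d[4], d[3]))
}
channel_mean <- function(x) channel_sum(x) / (dim(x)[1] * dim(x)[2] * dim(x)[4])

# normalized 1-D Gaussian window (standard SSIM window, sigma 1.5 at size 11)
gaussianWindow <- function(size, sigma = 1.5) {
  stopifnot(size %% 2 == 1, size >= 3)
  r <- seq_len(size) - (size + 1) / 2
  k <- exp(-(r^2) / (2 * sigma^2))
  k / sum(k)
}

# evaluate `code` under a private RNG stream, restoring the caller's RNG
# state afterwards (lazy evaluation: `code` runs after set.seed)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# FNV-style polynomial hash of a character scalar -> 8 hex digits.
# Integrity check for config/weight fingerprints, not cryptographic.
string_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.finite(x) && x >= min && x == round(x)
}
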