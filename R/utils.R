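# Internal helpers: seed splitting, scoped RNG, small numerics.

# Deterministic seed derivation: two rounds of a Lehmer step modulo the
# Mersenne prime 2^31-1, offset by the stream index. Keeps derived seeds in
# [1, 2^31-2] so set.seed() accepts them on any platform. All multiplications
# stay below 2^53 so the double arithmetic is exact.
split_seed <- function(seed, stream = 0L) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m) + 1
  s <- (48271 * s + as.numeric(stream)) %% m
  s <- (48271 * s + 11) %% m
  as.integer(s %% (m - 1) + 1)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Moment-based sample skewness g1 = m3 / m2^(3/2); 0 for degenerate input.
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# FNV-1a hash of a character scalar, as 8 hex digits; used to stamp output
# files with a config fingerprint without a digest dependency.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30  # keep in int range
    h <- (as.numeric(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
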