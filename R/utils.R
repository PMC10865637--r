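# Internal helpers: keyed RNG streams and small numeric utilities.
#
# All stochastic components of the package draw from streams keyed by
# (seed, entity identifiers) rather than from one global stream, so that
# adding a participant or re-ordering calls never perturbs draws belonging
# to other entities.

# 32-bit FNV-1a hash of a string, using double arithmetic kept exact by
# splitting the modular multiplication into 16-bit halves.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (byte in utf8ToInt(s)) {
    # xor the low byte
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(byte %% 256))
    # h * 16777619 mod 2^32
    lo16 <- h %% 65536
    hi16 <- h %/% 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# Derive a deterministic seed in [0, .Machine$integer.max) from arbitrary
# key components.  The unit-separator joint makes ("ab","c") != ("a","bc").
keyed_seed <- function(...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\x1f")
  as.integer(fnv1a32(key) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# One uniform draw from the stream keyed by the given components.
keyed_runif <- function(n, ...) {
  with_seed(keyed_seed(...), stats::runif(n))
}

# A permutation of 1..n from the stream keyed by the given components.
keyed_permutation <- function(n, ...) {
  with_seed(keyed_seed(...), sample.int(n))
}

# Truncated normal sampling by inverse-CDF; exact for the narrow
# truncations used here.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi <= plo) stop("infeasible truncation bounds [", lower, ", ", upper, "]")
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Tukey hinges (median-of-halves quartiles), as reported in the study
# descriptives; fivenum() implements exactly this convention.
tukey_quartiles <- function(x) {
  f <- stats::fivenum(x)
  c(q1 = f[2], median = f[3], q3 = f[4])
}

# Round half away from zero (report display convention for percentages;
# base round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
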