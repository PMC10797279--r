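# Internal helpers shared across modules: portable string hashing,
# RNG-stream isolation, seed fan-out, and small numeric utilities.

# FNV-1a 32-bit string hash, computed in double arithmetic so it is
# identical on every platform R runs on. Returns a value in [0, 2^31 - 1],
# usable directly as a set.seed() argument.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # keep in double, emulate 32-bit overflow of h * 16777619
    h <- (h * 16777619) %% 4294967296
  }
  h %% 2147483647
}

# Evaluate `expr` with its own RNG stream seeded at `seed`, restoring the
# caller's .Random.seed afterwards so library internals never perturb
# user-visible randomness.
with_rng <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage seed derivation from one global seed. The
# constant is a large prime; the modulus keeps the result a valid
# 32-bit seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.double(seed) * 48271 + fnv1a_hash(as.character(stage))) %% 2147483629
}

# uniform integer in [a, b]; immune to sample()'s scalar expansion
sample_int_range <- function(a, b) {
  if (a == b) return(as.integer(a))
  a + sample.int(b - a + 1L, 1L) - 1L
}

logit <- function(p) log(p / (1 - p))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# row-wise softmax of a matrix
softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
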