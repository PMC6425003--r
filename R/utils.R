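# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
# With seed = NULL the code runs on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Small stable string hash (FNV-1a, 31-bit) used to derive per-stage seeds
# and to fingerprint configurations; implemented in integer-safe doubles.
str_hash31 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2^31)
}

# Derive a reproducible sub-seed from a base seed and a stage name.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + str_hash31(stage)) %% 2147483647)
}
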