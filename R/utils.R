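# Internal helpers: deterministic string hashing for seed derivation,
# and lightweight logging.

# FNV-1a 32-bit hash of a character string, folded to a non-negative
# integer strictly below 2^31 so it is always a valid R RNG seed.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # XOR the low byte only (h may exceed .Machine$integer.max, so
    # bitwXor cannot be applied to h directly)
    b <- b %% 256
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619, done in two
    # 16-bit halves to stay within double precision exactness
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  h %% 2147483647
}

# Derive a reproducible child seed from a global seed and arbitrary keys.
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\x1f")
  as.integer(fnv1a_hash(key))
}

sp_log <- function(..., verbose = getOption("screenperm.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[screenperm] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
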