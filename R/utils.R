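# Internal helpers: classed conditions and local RNG scoping.

# All user-facing errors carry a condition class so callers (and tests) can
# distinguish failure modes without matching message text.
elm_abort <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "elm_error")))
}

elm_assert <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) elm_abort(class, msg, ...)
}

# Run `code` under set.seed(seed) without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed derivation from one master seed.
# Stage k in 0..15; result stays inside the 32-bit signed integer range.
derive_seed <- function(master_seed, k) {
  as.integer((as.double(master_seed) * 16 + k) %% 2147483647)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used to stamp pipeline artifacts with a config fingerprint.  The state is
# kept as a double in [0, 2^32); the multiply is split 16/16 to stay inside
# exact double-integer range.
fnv1a32 <- function(text) {
  bytes <- utf8ToInt(enc2utf8(paste(text, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)), sprintf("%04x", as.integer(h %% 65536)))
}

fmt_num <- function(x) sprintf("%.17g", x)
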