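# Internal helpers shared across modules.

# Classed errors so callers (and the pipeline) can branch on failure kind.
nim_stop <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "nimcdm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L), ...)
  )
  stop(cond)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    nim_stop("nimcdm_invalid_spec", "`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

check_square_numeric <- function(m, what) {
  if (!is_square(m) || !is.numeric(m)) {
    nim_stop("nimcdm_shape_error",
             sprintf("`%s` must be a square numeric matrix", what))
  }
  invisible(m)
}

# Tiny stable content hash (FNV-1a, 32 bit) used for report provenance.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
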