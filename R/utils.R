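# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded package functions never perturb the
#' caller's random stream.
#'
#' @param seed single integer seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (abs(seed) >= 2^31) {
    stop("seed must be an integer below 2^31", call. = FALSE)
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
  expr
}

# Cheap deterministic 32-bit FNV-1a hash of a character scalar, returned as a
# hex string. Used only for run-provenance fingerprints in reports.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit overflow multiply by the FNV prime 16777619, done in two halves
    # to stay within double precision
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- ((lo16 * 16777619) + (hi16 * 16777619 %% 65536) * 65536) %% 2^32
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# Stop with a consistent invalid-argument message.
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Derive a child seed from a base seed and a small offset, staying < 2^31.
child_seed <- function(seed, offset) {
  (as.double(seed) * 1009 + offset) %% 2147483647
}
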