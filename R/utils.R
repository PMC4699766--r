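# Internal helpers shared across the pipeline.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then restores
#' the caller's RNG state, so package functions never clobber the user's
#' random stream. A `NULL` seed leaves the current stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  code
}

#' Derive per-stage child seeds from one top-level seed
#'
#' All randomness in a multi-stage run flows from a single user seed; each
#' stage receives its own child seed so that changing one stage's sample size
#' does not perturb the draws of another. Children are kept below 2^31 - 1.
#'
#' @param seed Integer top-level seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
#' @examples
#' split_seed(1, 3)
split_seed <- function(seed, n) {
  stopifnot(n >= 1)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# FNV-1a 32-bit hash of a character string, returned as 8 hex digits.
# Used for config fingerprints in run manifests; stability matters,
# cryptographic strength does not.
fnv1a_hex <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b)) # keep in int range
    h <- (h + 2^30) %% 2^32                                   # undo offset
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Canonical JSON-ish serialization with recursively sorted keys, so the hash
# is invariant under key reordering in the config file.
canonical_string <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm)) {
      ord <- order(nm)
      x <- x[ord]
      nm <- nm[ord]
      inner <- vapply(seq_along(x), function(i) {
        paste0(nm[i], ":", canonical_string(x[[i]]))
      }, character(1))
      return(paste0("{", paste(inner, collapse = ","), "}"))
    }
    inner <- vapply(x, canonical_string, character(1))
    return(paste0("[", paste(inner, collapse = ","), "]"))
  }
  paste(format(x, digits = 15, trim = TRUE, scientific = FALSE), collapse = ",")
}

#' Fingerprint a configuration list
#'
#' Stable 8-hex-digit hash of a (possibly nested) configuration list,
#' invariant under reordering of named elements.
#'
#' @param config A list.
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  fnv1a_hex(canonical_string(config))
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
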