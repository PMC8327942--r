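#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministically derive a stream seed from a master seed and an index
# (line number, replicate number, pipeline stage, ...). Kept within the
# 32-bit integer range required by set.seed().
derive_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(index), length(index) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(master_seed) %% m)
  # two rounds of a multiplicative-congruential mix keep nearby
  # (seed, index) pairs well separated
  s <- (s * 48271 + as.double(index) * 16807 + 12345) %% m
  s <- (s * 69621 + 7) %% m
  as.integer(s)
}

#' Content fingerprint of a configuration object
#'
#' Canonicalizes an R list (recursively sorting names) and returns the MD5
#' hash of its JSON serialization, so that two configurations with the same
#' content yield the same fingerprint regardless of key order.
#'
#' @param x a list-like configuration object.
#' @return a length-one character MD5 string.
#' @export
config_fingerprint <- function(x) {
  canon <- canonicalize(x)
  json <- jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

canonicalize <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, canonicalize)
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
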