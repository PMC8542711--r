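# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All package-level determinism
# contracts go through this.
with_seed <- function(seed, code) {
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream index, kept inside
# the 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + 104729 * stream) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_pulseid <- function(msg, class) {
  rlang::abort(msg, class = c(class, "pulseid_error"))
}

# Euclidean norm of rows of a 2- or 3-column matrix.
row_norms <- function(m) sqrt(rowSums(m^2))
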