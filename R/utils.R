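# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
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
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Canonical key for an already lexicographically ordered edge (a < b).
edge_key <- function(a, b) paste(a, b, sep = "\t")

# Lexicographic sort key for a member set (members assumed sorted).
member_key <- function(members) paste(members, collapse = "\t")

stopifnot_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single non-missing number", call. = FALSE)
  }
}
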