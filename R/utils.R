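#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# All permutations of 1..n as a list of integer vectors, in lexicographic
# order so the identity (chronological) permutation comes first.
all_permutations <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1L)
  n <- as.integer(n)
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    for (p in rest) {
      tail <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, tail[p])
    }
  }
  out
}

# Number of pairwise inversions of a permutation relative to identity;
# used as a "distance from chronological order" tie-break.
count_inversions <- function(perm) {
  n <- length(perm)
  if (n < 2L) return(0L)
  inv <- 0L
  for (i in seq_len(n - 1L)) {
    inv <- inv + sum(perm[(i + 1L):n] < perm[i])
  }
  inv
}

# Derive a child RNG seed from a base seed, kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1009 * as.double(offset)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
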