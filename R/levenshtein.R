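# Levenshtein edit distance.

#' Levenshtein distance between two strings
#'
#' Minimal number of single-character insertions, deletions and
#' substitutions transforming `a` into `b`. Computed by the generalized
#' edit-distance routine in base R (`utils::adist`) with unit costs.
#'
#' @param a,b character strings (vectorised; recycled pairwise).
#' @return integer vector of distances.
#' @export
#' @examples
#' levenshtein("ACGT", "ACGA")  # 1
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(integer(0))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- as.integer(utils::adist(a[i], b[i])[1L, 1L])
  }
  out
}
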