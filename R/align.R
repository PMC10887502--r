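# Desk-scale read placement: exact k-mer seeding plus Levenshtein
# verification of the spanned window. This is deliberately not a
# general-purpose aligner (external aligners remain pluggable via SAM/BAM
# input); it is sufficient for amplicon reads against the circularized
# mitochondrial reference and against a small NUMT catalogue.

#' Build an exact k-mer index of a reference string
#'
#' @param sequence reference sequence (single string), e.g. the output of
#'   [circularize_reference()].
#' @param k k-mer size; the default 15 makes random collisions negligible at
#'   mitogenome scale.
#' @return an object of class `kmer_index`.
#' @export
kmer_index <- function(sequence, k = 15L) {
  k <- as.integer(k)
  n <- nchar(sequence)
  if (n < k) stop_config("reference shorter than k = %d", k)
  kmers <- substring(sequence, 1:(n - k + 1L), k:n)
  structure(list(sequence = sequence, length = n, k = k, kmers = kmers),
            class = "kmer_index")
}

#' Place reads on a reference by seeding and Levenshtein verification
#'
#' Each read is seeded with exact k-mers taken at staggered offsets; the
#' first seed hit implies a candidate start, which is verified by the
#' Levenshtein distance between the read and the reference window of the
#' same length. A read is mapped when that distance is at most
#' `max_dist_frac` of its length. A read is soft-clipped when more than two
#' terminal bases fall outside the reference span (mirroring SAM semantics
#' without a full aligner).
#'
#' @param seqs character vector of read sequences.
#' @param index a [kmer_index()] (or a reference string, indexed on the fly).
#' @param max_dist_frac verification ceiling as a fraction of read length.
#' @param seed_starts offsets (1-based) at which seed k-mers are taken.
#' @return data frame with one row per read: `mapped`, `start` (1-based on
#'   the indexed sequence; `NA` if unmapped), `lev` (`Inf` if unmapped) and
#'   `soft_clipped`.
#' @export
align_to_reference <- function(seqs, index, max_dist_frac = 0.25,
                               seed_starts = c(1L, 16L, 31L, 46L, 61L)) {
  if (!inherits(index, "kmer_index")) index <- kmer_index(index)
  n <- length(seqs)
  k <- index$k
  len <- nchar(seqs)
  start <- rep(NA_integer_, n)
  for (o in seed_starts) {
    todo <- which(is.na(start) & len >= o + k - 1L)
    if (!length(todo)) break
    seed <- substring(seqs[todo], o, o + k - 1L)
    hit <- match(seed, index$kmers)
    got <- !is.na(hit)
    start[todo[got]] <- hit[got] - o + 1L
  }
  lev <- rep(Inf, n)
  clipped <- rep(FALSE, n)
  mapped <- rep(FALSE, n)
  hasstart <- which(!is.na(start))
  for (i in hasstart) {
    s <- start[i]; e <- s + len[i] - 1L
    clip <- max(0L, 1L - s) + max(0L, e - index$length)
    clipped[i] <- clip > 2L
    ws <- max(1L, s); we <- min(index$length, e)
    if (we < ws) next
    window <- substr(index$sequence, ws, we)
    d <- utils::adist(seqs[i], window)[1L, 1L]
    lev[i] <- d
    mapped[i] <- d <= ceiling(max_dist_frac * len[i])
  }
  data.frame(mapped = mapped, start = start, lev = lev,
             soft_clipped = clipped)
}

# Map a 1-based coordinate on the padded (circularized) reference back into
# [1, L] on the circular molecule.
wrap_position <- function(pos, L) ((pos - 1L) %% L) + 1L
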