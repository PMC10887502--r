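# Noise reduction ahead of deconvolution: paired-read error correction,
# primer trimming, and NUMT removal by differential alignment.

#' Construct a paired-read set
#'
#' @param id fragment identifiers (unique).
#' @param seq1,qual1 forward read sequences and Phred+33 quality strings.
#' @param seq2,qual2 reverse read sequences/qualities (reverse strand by
#'   convention).
#' @return data frame of class `read_pairs`.
#' @export
read_pairs <- function(id, seq1, qual1, seq2, qual2) {
  if (anyDuplicated(id)) stop_data("duplicate read ids in pair set")
  if (any(nchar(seq1) != nchar(qual1)) || any(nchar(seq2) != nchar(qual2))) {
    stop_data("sequence and quality lengths differ")
  }
  structure(data.frame(id = as.character(id), seq1 = seq1, qual1 = qual1,
                       seq2 = seq2, qual2 = qual2, stringsAsFactors = FALSE),
            class = c("read_pairs", "data.frame"))
}

as_read_pairs <- function(df) {
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            class = c("read_pairs", "data.frame"))
}

# Find the overlap offset of rc(read2) within read1 coordinates.
# Offset o means: base 1 of rc2 sits at position o of read1 (o may be < 1).
# Returns c(offset, mismatches) or NULL when no acceptable overlap exists.
find_overlap <- function(s1, s2, min_overlap = 20L, min_identity = 0.75) {
  l1 <- nchar(s1); l2 <- nchar(s2)
  cands <- integer(0)
  for (o in c(1L, 16L, 31L, 46L, 61L)) {
    if (l2 >= o + 14L) {
      p <- regexpr(substr(s2, o, o + 14L), s1, fixed = TRUE)
      if (p > 0L) cands <- c(cands, p - o + 1L)
    }
  }
  for (o in c(1L, 16L, 31L)) {
    if (l1 >= o + 14L) {
      p <- regexpr(substr(s1, o, o + 14L), s2, fixed = TRUE)
      if (p > 0L) cands <- c(cands, o - p + 1L)
    }
  }
  cands <- unique(cands)
  if (!length(cands)) {
    cands <- seq(min_overlap - l2 + 1L, l1 - min_overlap + 1L)
  }
  best <- NULL; best_matches <- -1L
  for (o in cands) {
    a <- max(1L, o); b <- min(l1, o + l2 - 1L)
    ov <- b - a + 1L
    if (ov < min_overlap) next
    mm <- sum(charToRaw(substr(s1, a, b)) != charToRaw(substr(s2, a - o + 1L, b - o + 1L)))
    if (ov - mm > best_matches) { best_matches <- ov - mm; best <- c(o, mm, ov) }
  }
  if (is.null(best)) return(NULL)
  if ((best[3] - best[2]) / best[3] < min_identity) return(NULL)
  best[1:2]
}

#' Correct sequencing errors within read-pair overlaps
#'
#' Both mates of an amplicon pair observe the same molecule, so within their
#' overlap a disagreement means at least one call is wrong. The reverse read
#' is reverse-complemented, the mates are overlap-aligned (ungapped,
#' maximising matches, minimum overlap `min_overlap`), and if they disagree
#' at two or fewer positions each disagreeing call is replaced in both mates
#' by the call with the higher quality score (ties keep read 1). Pairs with
#' more than two disagreements, or with no acceptable overlap, pass through
#' unchanged and are counted.
#'
#' @param pairs a [read_pairs()] data frame.
#' @param min_overlap minimum acceptable overlap in bases.
#' @return list with elements `pairs` (corrected [read_pairs()]), `offset`
#'   (position of the first base of revcomp(read2) in read-1 coordinates;
#'   `NA` when no overlap was found), `mismatches`, and `metrics`.
#' @export
correct_pairs <- function(pairs, min_overlap = 20L) {
  n <- nrow(pairs)
  if (n == 0L) {
    return(list(pairs = pairs, offset = integer(0), mismatches = integer(0),
                metrics = list(pairs_in = 0L, pairs_corrected = 0L,
                               pairs_no_overlap = 0L, pairs_discordant = 0L)))
  }
  rc2 <- revcomp(pairs$seq2)
  rq2 <- str_reverse(pairs$qual2)
  s1 <- pairs$seq1; q1 <- pairs$qual1
  offset <- rep(NA_integer_, n)
  mism <- rep(NA_integer_, n)
  touched <- logical(n)
  for (i in seq_len(n)) {
    hit <- find_overlap(s1[i], rc2[i], min_overlap)
    if (is.null(hit)) next
    offset[i] <- hit[1]; mism[i] <- hit[2]
    if (hit[2] == 0L || hit[2] > 2L) next
    o <- hit[1]
    a <- max(1L, o); b <- min(nchar(s1[i]), o + nchar(rc2[i]) - 1L)
    pos <- a:b
    d <- pos[charToRaw(substr(s1[i], a, b)) != charToRaw(substr(rc2[i], a - o + 1L, b - o + 1L))]
    for (p in d) {
      p2 <- p - o + 1L
      qa <- phred_to_int(substr(q1[i], p, p))
      qb <- phred_to_int(substr(rq2[i], p2, p2))
      if (qb > qa) {
        substr(s1[i], p, p) <- substr(rc2[i], p2, p2)
        substr(q1[i], p, p) <- substr(rq2[i], p2, p2)
      } else {
        substr(rc2[i], p2, p2) <- substr(s1[i], p, p)
        substr(rq2[i], p2, p2) <- substr(q1[i], p, p)
      }
    }
    touched[i] <- TRUE
  }
  out <- pairs
  out$seq1 <- s1; out$qual1 <- q1
  if (any(touched)) {
    out$seq2[touched] <- revcomp(rc2[touched])
    out$qual2[touched] <- str_reverse(rq2[touched])
  }
  list(pairs = as_read_pairs(out), offset = offset, mismatches = mism,
       metrics = list(pairs_in = n,
                      pairs_corrected = sum(touched),
                      pairs_no_overlap = sum(is.na(offset)),
                      pairs_discordant = sum(!is.na(mism) & mism > 2L)))
}

#' Correct a single read pair
#' @param pair one-row [read_pairs()] data frame.
#' @param min_overlap minimum acceptable overlap in bases.
#' @return the corrected one-row [read_pairs()] data frame.
#' @export
correct_pair <- function(pair, min_overlap = 20L) {
  correct_pairs(as_read_pairs(pair[1, , drop = FALSE]), min_overlap)$pairs
}

#' Merge corrected mates into single fragment records
#'
#' Uses the overlap offsets from [correct_pairs()] (or
#' [preprocess_pipeline()]) to concatenate each pair into one fragment
#' sequence; within the overlap the (corrected) read-1 call is used. Pairs
#' without an acceptable overlap contribute read 1 only.
#'
#' @param corrected list with `pairs` and `offset`, as returned by
#'   [correct_pairs()] or [preprocess_pipeline()].
#' @return data frame `id`, `seq`, `qual`, `merged`.
#' @export
merge_pairs <- function(corrected) {
  pairs <- corrected$pairs
  offset <- corrected$offset
  n <- nrow(pairs)
  rc2 <- revcomp(pairs$seq2)
  rq2 <- str_reverse(pairs$qual2)
  seq <- character(n); qual <- character(n)
  for (i in seq_len(n)) {
    o <- offset[i]
    if (is.na(o)) { seq[i] <- pairs$seq1[i]; qual[i] <- pairs$qual1[i]; next }
    l1 <- nchar(pairs$seq1[i]); l2 <- nchar(rc2[i])
    pre_s <- if (o < 1L) substr(rc2[i], 1L, 1L - o) else ""
    pre_q <- if (o < 1L) substr(rq2[i], 1L, 1L - o) else ""
    post_s <- if (o + l2 - 1L > l1) substr(rc2[i], l1 - o + 2L, l2) else ""
    post_q <- if (o + l2 - 1L > l1) substr(rq2[i], l1 - o + 2L, l2) else ""
    seq[i] <- paste0(pre_s, pairs$seq1[i], post_s)
    qual[i] <- paste0(pre_q, pairs$qual1[i], post_q)
  }
  data.frame(id = pairs$id, seq = seq, qual = qual, merged = !is.na(offset),
             stringsAsFactors = FALSE)
}

# IUPAC degenerate-base expansion --------------------------------------------

iupac_table <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

expand_degenerate <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  opts <- lapply(chars, function(ch) {
    v <- iupac_table[[ch]]
    if (is.null(v)) stop_data("invalid base '%s' in primer sequence", ch)
    v
  })
  apply(do.call(expand.grid, c(rev(opts), stringsAsFactors = FALSE)), 1L,
        function(r) paste(rev(r), collapse = ""))
}

#' Construct a primer set
#'
#' Degenerate positions (IUPAC codes) are expanded into explicit sequence
#' variants at construction time.
#'
#' @param primer_id identifiers (one per primer).
#' @param sequence primer sequences, IUPAC codes allowed.
#' @param terminus expected terminus for the forward-strand occurrence:
#'   `"5p"`, `"3p"` or `"either"`.
#' @return data frame of class `primer_set` with one row per expanded
#'   variant.
#' @export
primer_set <- function(primer_id, sequence, terminus = "either") {
  terminus <- rep_len(terminus, length(primer_id))
  if (!all(terminus %in% c("5p", "3p", "either"))) {
    stop_config("primer terminus must be one of '5p', '3p', 'either'")
  }
  rows <- lapply(seq_along(primer_id), function(i) {
    vars <- expand_degenerate(sequence[i])
    data.frame(primer_id = primer_id[i], sequence = vars,
               terminus = terminus[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(!nzchar(out$sequence))) stop_data("empty primer sequence")
  structure(out, class = c("primer_set", "data.frame"))
}

#' Read a primer set from a TSV file
#'
#' Columns: primer_id, sequence, terminus (header optional).
#'
#' @param path input file.
#' @return a [primer_set()].
#' @export
read_primer_set <- function(path) {
  if (!file.exists(path)) stop_config("primer file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (identical(tolower(df[1, 1]), "primer_id")) df <- df[-1, , drop = FALSE]
  if (ncol(df) < 3L) stop_data("primer file needs columns primer_id, sequence, terminus")
  primer_set(df[[1]], df[[2]], df[[3]])
}

# Candidate occurrences per read end: a primer variant itself at its stated
# terminus and its reverse complement at the opposite terminus.
primer_candidates <- function(primers) {
  fwd5 <- primers$terminus %in% c("5p", "either")
  fwd3 <- primers$terminus %in% c("3p", "either")
  block <- function(keep, seqs, end) {
    data.frame(primer_id = primers$primer_id[keep], sequence = seqs,
               end = rep_len(end, sum(keep)), stringsAsFactors = FALSE)
  }
  rbind(
    block(fwd5, primers$sequence[fwd5], "5p"),
    block(fwd3, primers$sequence[fwd3], "3p"),
    block(fwd5, revcomp(primers$sequence[fwd5]), "3p"),
    block(fwd3, revcomp(primers$sequence[fwd3]), "5p")
  )
}

# Vectorised mismatch count between equal-length string vector and pattern.
terminal_mismatches <- function(frag, pattern) {
  m <- nchar(pattern)
  mm <- integer(length(frag))
  for (j in seq_len(m)) {
    mm <- mm + (substring(frag, j, j) != substring(pattern, j, j))
  }
  mm
}

#' Trim primer sequences from read termini
#'
#' The longest primer variant (or its reverse complement) matching within
#' `max_mismatch` at the 5' and/or 3' terminus is removed. Interior
#' occurrences are left untouched.
#'
#' @param seqs character vector of read sequences (a quality vector of the
#'   same shape may be passed via `quals` to be trimmed in step).
#' @param primers a [primer_set()].
#' @param max_mismatch allowed mismatches per terminal occurrence.
#' @param quals optional quality strings trimmed alongside.
#' @return list with `seqs` (trimmed), `quals` (or `NULL`), and `report`
#'   (data frame: read index, end, primer_id, bases removed).
#' @export
trim_primers <- function(seqs, primers, max_mismatch = 1L, quals = NULL) {
  n <- length(seqs)
  report <- list()
  if (n == 0L || is.null(primers) || nrow(primers) == 0L) {
    return(list(seqs = seqs, quals = quals,
                report = data.frame(read = integer(0), end = character(0),
                                    primer_id = character(0),
                                    bases = integer(0))))
  }
  cands <- primer_candidates(primers)
  len <- nchar(seqs)
  for (end in c("5p", "3p")) {
    cc <- cands[cands$end == end, , drop = FALSE]
    cc <- cc[order(-nchar(cc$sequence)), , drop = FALSE]  # longest wins
    cut <- integer(n)   # bases to remove at this end
    hit_id <- rep(NA_character_, n)
    for (r in seq_len(nrow(cc))) {
      m <- nchar(cc$sequence[r])
      elig <- which(cut == 0L & len >= m + 1L)
      if (!length(elig)) next
      frag <- if (end == "5p") substring(seqs[elig], 1L, m)
              else substring(seqs[elig], len[elig] - m + 1L, len[elig])
      mm <- terminal_mismatches(frag, cc$sequence[r])
      got <- elig[mm <= max_mismatch]
      cut[got] <- m
      hit_id[got] <- cc$primer_id[r]
    }
    hits <- which(cut > 0L)
    if (length(hits)) {
      if (end == "5p") {
        seqs[hits] <- substring(seqs[hits], cut[hits] + 1L, len[hits])
        if (!is.null(quals)) quals[hits] <- substring(quals[hits], cut[hits] + 1L, len[hits])
      } else {
        seqs[hits] <- substring(seqs[hits], 1L, len[hits] - cut[hits])
        if (!is.null(quals)) quals[hits] <- substring(quals[hits], 1L, len[hits] - cut[hits])
      }
      len <- nchar(seqs)
      report[[end]] <- data.frame(read = hits, end = end,
                                  primer_id = hit_id[hits],
                                  bases = cut[hits], stringsAsFactors = FALSE)
    }
  }
  rep_df <- if (length(report)) do.call(rbind, report) else
    data.frame(read = integer(0), end = character(0),
               primer_id = character(0), bases = integer(0))
  rownames(rep_df) <- NULL
  list(seqs = seqs, quals = quals, report = rep_df)
}

#' Identify candidate NUMT reads from nuclear alignments
#'
#' A read is a candidate nuclear-mitochondrial segment (NUMT) read when it
#' maps to the nuclear reference without soft-clipping at a Levenshtein
#' distance below three.
#'
#' @param alignments data frame with columns `read_id`, `mapped`,
#'   `soft_clipped`, `lev` (use `Inf` for unmapped reads).
#' @return character vector of candidate read ids.
#' @export
numt_candidates <- function(alignments) {
  with(alignments, read_id[mapped & !soft_clipped & lev < 3])
}

#' Classify candidate NUMT reads for removal
#'
#' A candidate is removed when its Levenshtein distance to the nuclear
#' reference is strictly less than its distance to the mitochondrial
#' reference; ties keep the read.
#'
#' @param candidates character vector of candidate read ids.
#' @param nuc_dist,mito_dist named numeric vectors of distances (`Inf` for
#'   reads that fail to align to a reference).
#' @return character vector of read ids to remove.
#' @export
classify_numts <- function(candidates, nuc_dist, mito_dist) {
  if (!length(candidates)) return(character(0))
  missing <- setdiff(candidates, intersect(names(nuc_dist), names(mito_dist)))
  if (length(missing)) {
    stop("NUMT classification: candidate(s) missing a distance: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  candidates[nuc_dist[candidates] < mito_dist[candidates]]
}

#' Run the full preprocessing stage
#'
#' Fixed stage order: pair error correction, primer trimming, NUMT
#' identification and removal. A pair is removed when either mate is
#' classified as a NUMT read. Metrics mirror the usual preprocessing count
#' reports (input fragments, candidate NUMTs, NUMTs removed).
#'
#' @param pairs a [read_pairs()] data frame.
#' @param primers optional [primer_set()].
#' @param mito a [mito_reference()].
#' @param nuclear optional nuclear reference: named character vector of
#'   sequences (e.g. a mini NUMT catalogue) or a FASTA path. `NULL` skips
#'   NUMT filtering.
#' @param min_overlap,primer_max_mismatch,pad,k tuning knobs for the
#'   component stages.
#' @return object of class `preprocess_result`: `pairs` (filtered),
#'   `offset`/`mismatches` (overlap bookkeeping for the surviving pairs),
#'   `removed_ids`, `trim_report`, `metrics`.
#' @export
preprocess_pipeline <- function(pairs, primers = NULL, mito, nuclear = NULL,
                                min_overlap = 20L, primer_max_mismatch = 1L,
                                pad = 200L, k = 15L) {
  metrics <- list(input_fragments = nrow(pairs))
  corr <- correct_pairs(pairs, min_overlap)
  metrics <- c(metrics, corr$metrics[-1])
  cur <- corr$pairs

  tr1 <- trim_primers(cur$seq1, primers, primer_max_mismatch, cur$qual1)
  tr2 <- trim_primers(cur$seq2, primers, primer_max_mismatch, cur$qual2)
  cur$seq1 <- tr1$seqs; cur$qual1 <- tr1$quals
  cur$seq2 <- tr2$seqs; cur$qual2 <- tr2$quals
  metrics$reads_trimmed <- length(unique(tr1$report$read)) +
    length(unique(tr2$report$read))
  metrics$bases_trimmed <- sum(tr1$report$bases) + sum(tr2$report$bases)

  removed <- character(0)
  metrics$numt_candidates <- 0L
  metrics$numts_removed <- 0L
  if (!is.null(nuclear) && nrow(cur)) {
    if (is.character(nuclear) && length(nuclear) == 1L && file.exists(nuclear)) {
      set <- Biostrings::readDNAStringSet(nuclear)
      nuclear <- stats::setNames(as.character(set), names(set))
    }
    # Concatenate catalogue records with an N spacer so no k-mer spans two
    # records; N never matches a read k-mer.
    nuc_seq <- paste(unlist(nuclear), collapse = strrep("N", k))
    nuc_idx <- kmer_index(nuc_seq, k)
    reads <- c(cur$seq1, revcomp(cur$seq2))
    read_id <- c(paste0(cur$id, "/1"), paste0(cur$id, "/2"))
    nal <- align_to_reference(reads, nuc_idx)
    nal$read_id <- read_id
    cand <- numt_candidates(nal)
    metrics$numt_candidates <- length(cand)
    if (length(cand)) {
      mito_idx <- kmer_index(circularize_reference(mito, pad), k)
      ci <- match(cand, read_id)
      mal <- align_to_reference(reads[ci], mito_idx)
      nuc_dist <- stats::setNames(nal$lev[ci], cand)
      mito_dist <- stats::setNames(mal$lev, cand)
      removed_reads <- classify_numts(cand, nuc_dist, mito_dist)
      removed <- unique(sub("/[12]$", "", removed_reads))
      metrics$numts_removed <- length(removed)
    }
  }
  keep <- !(cur$id %in% removed)
  metrics$fragments_out <- sum(keep)
  structure(list(pairs = as_read_pairs(cur[keep, , drop = FALSE]),
                 offset = corr$offset[keep],
                 mismatches = corr$mismatches[keep],
                 removed_ids = removed,
                 trim_report = list(read1 = tr1$report, read2 = tr2$report),
                 metrics = metrics),
            class = "preprocess_result")
}
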