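# File I/O: paired FASTQ (via Biostrings) and SAM/BAM alignments
# (via Rsamtools).

strip_mate_suffix <- function(ids) sub("[/ ][12]$", "", sub("\\s.*$", "", ids))

#' Read a pair of FASTQ files into a read-pair set
#'
#' Phred+33 decoding; gzip transparent. Mates are matched by record order
#' and checked by id (a trailing `/1`, `/2` is ignored).
#'
#' @param path1,path2 FASTQ paths (optionally .gz).
#' @return a [read_pairs()] data frame.
#' @export
read_fastq_pair <- function(path1, path2) {
  for (p in c(path1, path2)) {
    if (!file.exists(p)) stop_config("FASTQ file not found: %s", p)
  }
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2)) {
    stop_data("desynchronized mates: %d records in %s but %d in %s",
              length(r1), path1, length(r2), path2)
  }
  id1 <- strip_mate_suffix(names(r1))
  id2 <- strip_mate_suffix(names(r2))
  bad <- which(id1 != id2)
  if (length(bad)) {
    stop_data("mate id mismatch at record %d: '%s' vs '%s'",
              bad[1], id1[bad[1]], id2[bad[1]])
  }
  read_pairs(id1,
             as.character(r1), as.character(S4Vectors::mcols(r1)$qualities),
             as.character(r2), as.character(S4Vectors::mcols(r2)$qualities))
}

#' Write a read-pair set as two FASTQ files
#'
#' @param pairs a [read_pairs()] data frame.
#' @param path1,path2 output paths.
#' @param compress write gzip-compressed output.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pair <- function(pairs, path1, path2, compress = FALSE) {
  w <- function(seqs, quals, ids, path) {
    set <- Biostrings::DNAStringSet(seqs)
    names(set) <- ids
    Biostrings::writeXStringSet(set, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = compress)
  }
  w(pairs$seq1, pairs$qual1, pairs$id, path1)
  w(pairs$seq2, pairs$qual2, pairs$id, path2)
  invisible(c(path1, path2))
}

# Reference width of a CIGAR string (M/D/N/=/X consume reference).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read alignment records from SAM/BAM
#'
#' SAM input is converted on the fly. Soft-clipping is taken from the CIGAR
#' string; when a reference is supplied the Levenshtein distance of each
#' mapped read to the reference span it is aligned to is recomputed from
#' the sequences (aligner tags are not trusted), giving bit-reproducible
#' distances across aligner dialects. Unmapped reads carry an infinite
#' distance sentinel.
#'
#' @param path SAM or BAM file with a header.
#' @param reference optional [mito_reference()] (or a plain sequence
#'   string, e.g. a padded reference) for distance recomputation.
#' @return data frame: `read_id`, `mapped`, `pos`, `soft_clipped`, `lev`,
#'   `seq`, `qual`.
#' @export
read_alignments <- function(path, reference = NULL) {
  if (!file.exists(path)) stop_config("alignment file not found: %s", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "cigar", "seq", "qual", "pos")))[[1]]
  if (!length(res$qname)) {
    stop_data("no alignment records in %s", path)
  }
  mapped <- !bitwAnd(res$flag, 4L)
  seqs <- as.character(res$seq)
  lev <- rep(Inf, length(seqs))
  if (!is.null(reference)) {
    refseq <- if (inherits(reference, "mito_reference")) reference$sequence else reference
    rw <- cigar_ref_width(res$cigar)
    for (i in which(mapped & !is.na(res$pos) & !is.na(rw))) {
      window <- substr(refseq, res$pos[i], res$pos[i] + rw[i] - 1L)
      lev[i] <- utils::adist(seqs[i], window)[1L, 1L]
    }
  }
  soft <- mapped & !is.na(res$cigar) & grepl("S", res$cigar, fixed = TRUE)
  data.frame(read_id = res$qname, mapped = mapped, pos = res$pos,
             soft_clipped = soft,
             lev = lev, seq = seqs, qual = as.character(res$qual),
             stringsAsFactors = FALSE)
}
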