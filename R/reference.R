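# Mitochondrial reference sequence: container, FASTA I/O, circularization.

#' Create a mitochondrial reference object
#'
#' The human mitogenome is a circular molecule; the canonical rCRS numbering
#' is 1-based over 16,569 bases. A `mito_reference` stores the linear
#' sequence together with the convention that coordinates wrap modulo its
#' length. Circularity is only materialised at alignment time via
#' [circularize_reference()].
#'
#' @param sequence single character string of A/C/G/T/N bases.
#' @param name sequence name.
#' @return an object of class `mito_reference` with fields `name`,
#'   `sequence`, `length` and `circular` (always `TRUE`).
#' @export
#' @examples
#' ref <- mito_reference("ACGTACGTAC", name = "toy")
#' ref$length
mito_reference <- function(sequence, name = "chrM") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop_data("reference sequence must be a single non-empty string")
  }
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop_data("reference sequence contains characters other than A/C/G/T/N")
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         circular = TRUE),
    class = "mito_reference"
  )
}

#' Read a mitochondrial reference from FASTA
#'
#' @param path FASTA file with a single record.
#' @return a [mito_reference()].
#' @export
read_mito_reference <- function(path) {
  if (!file.exists(path)) stop_config("reference file not found: %s", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 1L) stop_data("no sequences in FASTA: %s", path)
  mito_reference(as.character(set[[1L]]), name = sub("\\s.*$", "", names(set)[1L]))
}

#' Write a reference to FASTA
#' @param ref a [mito_reference()] (or any list with `name` and `sequence`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path) {
  if (inherits(ref, "mito_reference")) {
    set <- Biostrings::DNAStringSet(stats::setNames(ref$sequence, ref$name))
  } else {
    set <- Biostrings::DNAStringSet(unlist(ref))
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @export
print.mito_reference <- function(x, ...) {
  cat(sprintf("<mito_reference> %s: %d bp (circular)\n", x$name, x$length))
  invisible(x)
}

#' Linearise a circular reference with a padding overhang
#'
#' Appends the first `pad` bases of the sequence to its end so that amplicons
#' spanning the origin (the control region in rCRS numbering) align
#' contiguously. Alignment coordinates beyond the reference length are mapped
#' back into `[1, L]` modulo `L` by the alignment routines.
#'
#' @param ref a [mito_reference()].
#' @param pad number of bases to append, `0 < pad < L`. The default 200 bases
#'   exceeds the longest amplicon produced by whole-mitogenome panels.
#' @return a character string of length `L + pad`.
#' @export
circularize_reference <- function(ref, pad = 200L) {
  pad <- as.integer(pad)
  if (is.na(pad) || pad <= 0L || pad >= ref$length) {
    stop_config("'pad' must satisfy 0 < pad < reference length (%d)", ref$length)
  }
  paste0(ref$sequence, substr(ref$sequence, 1L, pad))
}

#' Apply substitution variants to a reference sequence
#'
#' Builds an individual's mitogenome string from the reference and a variant
#' table. Only substitutions alter the sequence; insertions and deletions are
#' carried through parsing but do not participate in genome construction or
#' likelihoods.
#'
#' @param ref a [mito_reference()].
#' @param variants variant data frame as returned by [expected_variants()].
#' @return character string of length `ref$length`.
#' @export
apply_variants <- function(ref, variants) {
  seq <- ref$sequence
  if (is.null(variants) || !nrow(variants)) return(seq)
  subs <- variants[variants$kind == "substitution", , drop = FALSE]
  if (nrow(subs)) {
    if (any(subs$position < 1L | subs$position > ref$length)) {
      stop_data("variant position outside reference coordinates")
    }
    for (i in seq_len(nrow(subs))) {
      substr(seq, subs$position[i], subs$position[i]) <- subs$derived[i]
    }
  }
  seq
}
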