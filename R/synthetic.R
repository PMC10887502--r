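# Bundled synthetic study system: a 16,569-base reference-shaped sequence
# and a 24-node mini haplogroup tree with four clades. The shallow "H-like"
# clade deliberately contains single-SNP branches (H3a at 1018, H27 at
# 16093) so that spurious-haplogroup behaviour driven by private mutations
# or heteroplasmy can be constructed and studied.

#' Generate the synthetic mitochondrial reference sequence
#'
#' A seeded random 16,569-base sequence standing in for an rCRS-shaped
#' mitogenome (no licensed data is bundled). The copy under
#' `inst/extdata/synthetic_mito.fasta` is this function's output.
#'
#' @param length sequence length in bases.
#' @param seed generator seed; the default pins the bundled sequence.
#' @param name sequence name.
#' @return a [mito_reference()].
#' @export
synthetic_reference <- function(length = 16569L, seed = 20240131L,
                                name = "synthMT") {
  seq <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                                      replace = TRUE,
                                      prob = c(0.31, 0.31, 0.13, 0.25)),
                               collapse = ""))
  mito_reference(seq, name = name)
}

# topology: name, parent, diagnostic positions
mini_tree_topology <- function() {
  list(
    list("mt-MRCA", NA,    integer(0)),
    list("L0",  "mt-MRCA", c(263L, 750L, 1438L, 2706L, 4769L, 8860L)),
    list("L0a", "L0",      c(3594L, 5442L, 9042L)),
    list("L0a1","L0a",     c(10398L, 12705L)),
    list("L0b", "L0",      c(5603L, 9347L, 13276L)),
    list("L0c", "L0",      c(922L, 15301L)),
    list("M",   "mt-MRCA", c(489L, 10400L, 14783L, 15043L)),
    list("M7",  "M",       c(6455L, 9824L, 12091L)),
    list("M7a", "M7",      c(2772L, 16324L)),
    list("M8",  "M",       c(4715L, 7196L, 8584L)),
    list("M8a", "M8",      c(6179L, 14470L)),
    list("D4",  "M",       c(4883L, 5178L, 8414L)),
    list("R",   "mt-MRCA", c(11467L, 12372L)),
    list("B2",  "R",       c(8281L, 11177L, 16189L)),
    list("B2a", "B2",      13590L),
    list("U5",  "R",       c(3197L, 9477L, 13617L, 16270L)),
    list("U5a", "U5",      c(14793L, 16256L)),
    list("H",   "R",       c(7028L, 11719L)),
    list("H1",  "H",       3010L),
    list("H3",  "H",       6776L),
    list("H3a", "H3",      1018L),
    list("H27", "H",       16093L),
    list("H2",  "H",       4680L)
  )
}

transition <- c(A = "G", G = "A", C = "T", T = "C")

#' Generate the bundled mini haplogroup phylotree
#'
#' 23 haplogroups in four clades (deep L0 and M clades, an R clade, and a
#' shallow H clade with 1-SNP branches). Derived alleles are transitions of
#' the reference base, mirroring the mutational bias of real mtDNA. The copy
#' under `inst/extdata/mini_phylotree.tsv` is this function's output.
#'
#' @param reference a [mito_reference()], typically [synthetic_reference()].
#' @return a `phylotree` with the reference attached.
#' @export
synthetic_phylotree <- function(reference = synthetic_reference()) {
  topo <- mini_tree_topology()
  all_pos <- unlist(lapply(topo, `[[`, 3))
  stopifnot(!anyDuplicated(all_pos), all(all_pos <= reference$length))
  nodes <- list(); order <- character(0)
  for (entry in topo) {
    nm <- entry[[1]]; parent <- entry[[2]]; pos <- entry[[3]]
    if (length(pos)) {
      refb <- substring(reference$sequence, pos, pos)
      variants <- data.frame(position = pos, ref = refb,
                             derived = unname(transition[refb]),
                             kind = "substitution", back_mutation = FALSE,
                             stringsAsFactors = FALSE)
    } else variants <- empty_variants()
    nodes[[nm]] <- list(name = nm, parent = if (is.na(parent)) NA_character_ else parent,
                        variants = variants, known = FALSE)
    order <- c(order, nm)
  }
  structure(list(nodes = nodes, order = order, reference = reference),
            class = "phylotree")
}

#' Generate the bundled synthetic primer set
#'
#' Eight 21-base primers lifted from the synthetic reference (four forward
#' at 5', four reverse at 3'), one of them carrying a degenerate base, so
#' that terminal trimming has realistic material to act on.
#'
#' @param reference a [mito_reference()].
#' @return a [primer_set()].
#' @export
synthetic_primer_set <- function(reference = synthetic_reference()) {
  starts <- c(101L, 4201L, 8301L, 12401L)
  fwd <- substring(reference$sequence, starts, starts + 20L)
  rev_starts <- c(2201L, 6301L, 10401L, 14501L)
  rev <- revcomp(substring(reference$sequence, rev_starts, rev_starts + 20L))
  # one degenerate position in the first forward primer
  substr(fwd[1], 11, 11) <- "R"
  primer_set(c(sprintf("F%d", seq_along(starts)), sprintf("R%d", seq_along(rev_starts))),
             c(fwd, rev),
             c(rep("5p", 4), rep("3p", 4)))
}

#' Build a mini nuclear NUMT catalogue from the mitochondrial reference
#'
#' Each catalogue record is a nuclear-context sequence embedding a
#' mitochondria-derived segment that has diverged by one substitution every
#' `edit_spacing` bases. The spacing default guarantees that every
#' read-length window of the segment carries at least three edits, so true
#' mitochondrial reads can never be closer to the nuclear copy than to the
#' mitogenome, while reads generated from the nuclear copy (with up to two
#' additional errors) always are.
#'
#' @param reference a [mito_reference()].
#' @param n_segments number of NUMT records.
#' @param seg_length length of each mito-derived segment.
#' @param edit_spacing bases between consecutive NUMT edits.
#' @param flank random nuclear flank length on each side.
#' @param seed generator seed.
#' @return object of class `numt_catalogue`: `sequences` (named character),
#'   `segments` (data frame with the mito origin and the segment interval
#'   within each nuclear record).
#' @export
build_numt_catalogue <- function(reference, n_segments = 2L, seg_length = 600L,
                                 edit_spacing = 35L, flank = 300L,
                                 seed = 1L) {
  with_seed(seed, {
    sequences <- character(0)
    segments <- list()
    for (i in seq_len(n_segments)) {
      start <- sample.int(reference$length - seg_length, 1L)
      seg <- substr(reference$sequence, start, start + seg_length - 1L)
      edit_at <- seq(15L, seg_length, by = edit_spacing)
      for (p in edit_at) {
        cur <- substr(seg, p, p)
        substr(seg, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
      fl1 <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
      fl2 <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
      nm <- sprintf("numt_ctx_%d", i)
      sequences[nm] <- paste0(fl1, seg, fl2)
      segments[[i]] <- data.frame(name = nm, mito_start = start,
                                  seg_start = flank + 1L,
                                  seg_end = flank + seg_length,
                                  n_edits = length(edit_at),
                                  stringsAsFactors = FALSE)
    }
    structure(list(sequences = sequences, segments = do.call(rbind, segments)),
              class = "numt_catalogue")
  })
}

#' Path to a bundled data file
#' @param name file name under the package's `extdata`, or empty to list.
#' @return file path.
#' @export
mitodemix_file <- function(name = "") {
  system.file("extdata", name, package = "mitodemix", mustWork = nzchar(name))
}
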