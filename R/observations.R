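# Observation matrix: per-fragment observed alleles and error probabilities
# at phylogenetically informative positions.

# Substitution positions appearing in any node's defining variants.
substitution_positions <- function(tree) {
  pos <- unlist(lapply(tree$nodes, function(n) {
    n$variants$position[n$variants$kind == "substitution"]
  }), use.names = FALSE)
  sort(unique(as.integer(pos)))
}

# Expected allele matrix: positions x candidates, reference base unless the
# candidate's cumulative haplotype carries a substitution there.
expected_allele_matrix <- function(tree, candidates, positions, ref) {
  base_ref <- substring(ref$sequence, positions, positions)
  E <- matrix(base_ref, nrow = length(positions), ncol = length(candidates),
              dimnames = list(NULL, candidates))
  for (h in candidates) {
    v <- expected_variants(tree, h)
    v <- v[v$kind == "substitution", , drop = FALSE]
    if (!nrow(v)) next
    ix <- match(v$position, positions)
    ok <- !is.na(ix)
    E[ix[ok], h] <- v$derived[ok]
  }
  E
}

#' Build the observation matrix for deconvolution
#'
#' For every aligned fragment, records the observed base and Phred-derived
#' error probability at each diagnostic position it covers. Only
#' substitution-type diagnostic positions are used; `N` or gap calls at a
#' position are skipped for that fragment. Fragments covering no diagnostic
#' position are flagged uninformative; fragments that fail to align are
#' excluded and counted.
#'
#' @param fragments data frame with columns `id`, `seq`, `qual` and
#'   optionally `start` (1-based position on the padded reference produced
#'   by [circularize_reference()]). Without `start`, fragments are placed
#'   with the built-in k-mer aligner.
#' @param tree a `phylotree` (grafted knowns contribute their positions).
#' @param ref a [mito_reference()].
#' @param pad circularization pad used for alignment coordinates.
#' @return object of class `observation_matrix`: long table `obs`
#'   (`frag` index, `position` in 1..L, `base`, `eps`), fragment ids,
#'   informative flags, the positions used, and the aligned fragments
#'   (retained so observations can be rebuilt after grafting knowns).
#' @export
build_observations <- function(fragments, tree, ref, pad = 200L) {
  stopifnot(is.data.frame(fragments))
  n_in <- nrow(fragments)
  if (is.null(fragments$start)) {
    idx <- kmer_index(circularize_reference(ref, pad))
    al <- align_to_reference(fragments$seq, idx)
    fragments$start <- ifelse(al$mapped, al$start, NA_integer_)
  }
  excluded <- sum(is.na(fragments$start) | fragments$start < 1L)
  fragments <- fragments[!is.na(fragments$start) & fragments$start >= 1L, ,
                         drop = FALSE]
  positions <- substitution_positions(tree)
  L <- ref$length
  starts <- fragments$start
  ends <- starts + nchar(fragments$seq) - 1L
  frag <- integer(0); pos <- integer(0); off <- integer(0)
  for (p in positions) {
    for (pp in c(p, p + L)) {
      hit <- which(starts <= pp & ends >= pp)
      if (length(hit)) {
        frag <- c(frag, hit)
        pos <- c(pos, rep.int(p, length(hit)))
        off <- c(off, pp - starts[hit] + 1L)
      }
    }
  }
  if (length(frag)) {
    base <- substring(fragments$seq[frag], off, off)
    qch <- substring(fragments$qual[frag], off, off)
    eps <- phred_chars_to_eps(qch)
    keep <- base %in% c("A", "C", "G", "T")
    obs <- data.frame(frag = frag[keep], position = pos[keep],
                      base = base[keep], eps = eps[keep],
                      stringsAsFactors = FALSE)
    obs <- obs[order(obs$frag, obs$position), , drop = FALSE]
    rownames(obs) <- NULL
  } else {
    obs <- data.frame(frag = integer(0), position = integer(0),
                      base = character(0), eps = numeric(0))
  }
  informative <- seq_len(nrow(fragments)) %in% obs$frag
  structure(list(obs = obs,
                 fragment_ids = fragments$id,
                 informative = informative,
                 n_fragments = nrow(fragments),
                 n_excluded = excluded,
                 positions = positions,
                 fragments = fragments),
            class = "observation_matrix")
}

#' @export
print.observation_matrix <- function(x, ...) {
  cat(sprintf("<observation_matrix> %d fragments (%d informative, %d excluded), %d diagnostic positions, %d observations\n",
              x$n_fragments, sum(x$informative), x$n_excluded,
              length(x$positions), nrow(x$obs)))
  invisible(x)
}

#' Log-likelihood of one fragment under one haplogroup
#'
#' Independent-error model over the fragment's observed diagnostic
#' positions: a base agreeing with the haplogroup's expected allele
#' contributes `log(1 - eps)`; a disagreeing base contributes
#' `log(eps / 3)`. The expected allele is the haplogroup's derived allele at
#' positions in its cumulative variant set and the reference base elsewhere.
#'
#' @param obs_i data frame with columns `position`, `base`, `eps` for one
#'   fragment.
#' @param haplogroup candidate haplogroup name.
#' @param tree a `phylotree` whose `reference` is set.
#' @return log-probability (0 for an empty observation).
#' @export
fragment_log_likelihood <- function(obs_i, haplogroup, tree) {
  ref <- tree$reference
  if (is.null(ref)) stop_config("tree has no reference sequence attached")
  if (!nrow(obs_i)) return(0)
  E <- expected_allele_matrix(tree, haplogroup, obs_i$position, ref)
  match <- obs_i$base == E[, 1L]
  sum(ifelse(match, log1p(-obs_i$eps), log(obs_i$eps / 3)))
}

# N_informative x H log-likelihood matrix.
loglik_matrix <- function(obsmat, tree, candidates, ref = tree$reference) {
  if (is.null(ref)) stop_config("tree has no reference sequence attached")
  obs <- obsmat$obs
  if (!nrow(obs)) stop_data("nothing to deconvolute: zero informative fragments")
  frag_ids <- sort(unique(obs$frag))
  E <- expected_allele_matrix(tree, candidates, obsmat$positions, ref)
  pix <- match(obs$position, obsmat$positions)
  row <- match(obs$frag, frag_ids)
  lmatch <- log1p(-obs$eps)
  lmis <- log(obs$eps / 3)
  L <- matrix(0, nrow = length(frag_ids), ncol = length(candidates),
              dimnames = list(NULL, candidates))
  for (j in seq_along(candidates)) {
    contrib <- ifelse(obs$base == E[pix, j], lmatch, lmis)
    sums <- rowsum(contrib, row)
    L[as.integer(rownames(sums)), j] <- sums[, 1L]
  }
  attr(L, "frag_index") <- frag_ids
  L
}
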