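# Seeded in-silico data generation: sole-source amplicon read sets with
# sequencing error, point heteroplasmy and private mutations; ratio mixing
# by without-replacement subsetting; NUMT spiking; random reduction. Every
# generator routes its randomness through with_seed(), so identical
# config + seed yields byte-identical output.

new_manifest <- function(fragments, contributors, heteroplasmy = NULL,
                         numt_ids = character(0), seed = NULL) {
  structure(list(fragments = fragments, contributors = contributors,
                 heteroplasmy = heteroplasmy, numt_ids = numt_ids,
                 seed = seed),
            class = "truth_manifest")
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat(sprintf("<truth_manifest> %d fragments, %d contributor(s), %d NUMT read(s)\n",
              nrow(x$fragments), nrow(x$contributors), length(x$numt_ids)))
  print(x$contributors, row.names = FALSE)
  invisible(x)
}

# Inject substitution errors at a fixed per-base rate (expects an active
# seeded RNG from the caller).
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  len <- nchar(seqs)
  k <- stats::rbinom(length(seqs), len, rate)
  for (i in which(k > 0L)) {
    pos <- sample.int(len[i], k[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  seqs
}

#' Simulate a sole-source amplicon read set
#'
#' Emulates paired-end MPS sequencing of a single individual's mitogenome
#' with a whole-genome amplicon panel: amplicon-length fragments tiled
#' uniformly over the circular genome, 2x`read_length` paired reads with
#' independent per-base substitution errors at the rate implied by the
#' constant quality score, and point heteroplasmy emitted per covering
#' fragment (both mates of a fragment carry the same molecule, so a
#' heteroplasmic minor allele appears on both strands).
#'
#' @param reference a [mito_reference()].
#' @param tree a `phylotree` (used to resolve `haplogroup`).
#' @param haplogroup contributor haplogroup name, or `NULL` with `known`.
#' @param known optional [known_haplotype()] used instead of `haplogroup`.
#' @param private_variants optional extra variant tokens (private
#'   mutations), e.g. `c("1018G")`.
#' @param heteroplasmies optional data frame `position`, `minor_allele`,
#'   `maf` with MAF in (0, 0.5].
#' @param n_fragments number of fragments (read pairs).
#' @param read_length read length (default 150).
#' @param amplicon_mean,amplicon_sd,amplicon_range amplicon length model:
#'   normal with the given mean/sd, clamped to the range. The default mean
#'   of 167 bases matches small-amplicon whole-mitogenome panels.
#' @param quality constant Phred quality (default Q30).
#' @param error_rate per-base substitution error rate; defaults to
#'   `10^(-quality/10)`.
#' @param seed generator seed.
#' @param label contributor label used in read ids and the manifest.
#' @return list with `pairs` (a [read_pairs()]) and `manifest`
#'   (a `truth_manifest`).
#' @export
simulate_sole_source <- function(reference, tree, haplogroup = NULL,
                                 known = NULL, private_variants = NULL,
                                 heteroplasmies = NULL,
                                 n_fragments, read_length = 150L,
                                 amplicon_mean = 167, amplicon_sd = 15,
                                 amplicon_range = c(120L, 250L),
                                 quality = 30L, error_rate = NULL,
                                 seed = 1L, label = NULL) {
  if (n_fragments <= 0L) stop_config("'n_fragments' must be positive")
  if (is.null(haplogroup) && is.null(known)) {
    stop_config("supply 'haplogroup' or 'known'")
  }
  variants <- if (!is.null(known)) known$variants else expected_variants(tree, haplogroup)
  if (!is.null(known) && is.null(heteroplasmies)) heteroplasmies <- known$heteroplasmies
  if (!is.null(private_variants)) {
    pv <- if (is.character(private_variants)) {
      parse_variant_tokens(private_variants, reference)
    } else private_variants
    variants <- rbind(variants[!(variants$position %in% pv$position), , drop = FALSE], pv)
  }
  if (!is.null(heteroplasmies) && nrow(heteroplasmies)) {
    if (any(heteroplasmies$maf <= 0 | heteroplasmies$maf > 0.5)) {
      stop_config("heteroplasmy MAF must lie in (0, 0.5]")
    }
    clash <- intersect(heteroplasmies$position, variants$position)
    if (length(clash)) {
      stop_config("contradictory specification: fixed variant and heteroplasmy at position(s) %s",
                  paste(clash, collapse = ", "))
    }
  }
  label <- label %||% (if (!is.null(known)) known$sample_id else haplogroup)
  error_rate <- error_rate %||% 10^(-quality / 10)
  genome <- apply_variants(reference, variants)
  L <- reference$length
  pad <- amplicon_range[2]
  genome_pad <- paste0(genome, substr(genome, 1L, pad))

  with_seed(seed, {
    starts <- sample.int(L, n_fragments, replace = TRUE)
    lens <- as.integer(pmin(pmax(round(stats::rnorm(n_fragments, amplicon_mean,
                                                    amplicon_sd)),
                                 amplicon_range[1]), amplicon_range[2]))
    frags <- substring(genome_pad, starts, starts + lens - 1L)
    ends <- starts + lens - 1L

    het_truth <- NULL
    if (!is.null(heteroplasmies) && nrow(heteroplasmies)) {
      het_truth <- heteroplasmies
      het_truth$n_covering <- 0L
      het_truth$n_minor <- 0L
      for (j in seq_len(nrow(heteroplasmies))) {
        p <- heteroplasmies$position[j]
        for (pp in c(p, p + L)) {
          cov <- which(starts <= pp & ends >= pp)
          if (!length(cov)) next
          flip <- cov[stats::runif(length(cov)) < heteroplasmies$maf[j]]
          off <- pp - starts[flip] + 1L
          for (t in seq_along(flip)) {
            substr(frags[flip[t]], off[t], off[t]) <- heteroplasmies$minor_allele[j]
          }
          het_truth$n_covering[j] <- het_truth$n_covering[j] + length(cov)
          het_truth$n_minor[j] <- het_truth$n_minor[j] + length(flip)
        }
      }
    }

    r1len <- pmin(read_length, lens)
    seq1 <- substring(frags, 1L, r1len)
    seq2 <- revcomp(substring(frags, lens - r1len + 1L, lens))
    seq1 <- inject_errors(seq1, error_rate)
    seq2 <- inject_errors(seq2, error_rate)
    qchar <- int_to_phred(quality)
    qual <- strrep(qchar, r1len)
    ids <- sprintf("%s_%07d", label, seq_len(n_fragments))
    pairs <- read_pairs(ids, seq1, qual, seq2, qual)
    manifest <- new_manifest(
      fragments = data.frame(id = ids, origin = label,
                             start = wrap_position(starts, L), length = lens,
                             stringsAsFactors = FALSE),
      contributors = data.frame(label = label,
                                haplogroup = haplogroup %||% NA_character_,
                                n_fragments = n_fragments, proportion = 1,
                                stringsAsFactors = FALSE),
      heteroplasmy = het_truth, seed = seed)
    list(pairs = pairs, manifest = manifest)
  })
}

#' Per-source fragment counts for a mixture ratio
#'
#' Largest-remainder apportionment of `total` fragments over the ratio:
#' exact totals are preserved and the result is deterministic.
#'
#' @param ratio positive integer ratio, e.g. `c(1, 3)`.
#' @param total total fragment count.
#' @return integer vector of per-source counts summing to `total`.
#' @export
#' @examples
#' mixture_counts(c(1, 3), 720000)   # 180000 540000
mixture_counts <- function(ratio, total) {
  if (any(ratio <= 0)) stop_config("mixture ratio entries must be positive")
  quota <- total * ratio / sum(ratio)
  base <- floor(quota)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0L) {
    extra <- order(-(quota - base), seq_along(ratio))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Randomly subset a paired read set without replacement
#'
#' @param pairs a [read_pairs()] data frame.
#' @param n number of fragments to keep (`n <= nrow(pairs)`).
#' @param seed selection seed.
#' @return a [read_pairs()] with exactly `n` fragments, mate pairing
#'   preserved, all read ids distinct.
#' @export
subset_fastq <- function(pairs, n, seed = 1L) {
  if (n > nrow(pairs)) {
    stop_data("requested %d fragments but only %d available", n, nrow(pairs))
  }
  if (n == nrow(pairs)) idx <- with_seed(seed, sample.int(nrow(pairs)))
  else idx <- with_seed(seed, sample.int(nrow(pairs), n))
  as_read_pairs(pairs[idx, , drop = FALSE])
}

#' Combine sole-source read sets into an in-silico mixture
#'
#' Draws a without-replacement subset from each source at the per-source
#' counts given by [mixture_counts()] and interleaves the fragments in
#' seeded-shuffled order, so no downstream step can exploit file order.
#'
#' @param sources list of sole-source sets: each either a [read_pairs()] or
#'   a `list(pairs=, manifest=)` as returned by [simulate_sole_source()].
#' @param ratio positive integer ratio, one entry per source.
#' @param total total number of fragments in the mixture.
#' @param seed mixing seed.
#' @return list with `pairs` and a `truth_manifest` whose per-source counts
#'   match the ratio arithmetic exactly.
#' @export
mix_fastqs <- function(sources, ratio, total, seed = 1L) {
  if (length(sources) != length(ratio)) {
    stop_config("ratio length (%d) must match number of sources (%d)",
                length(ratio), length(sources))
  }
  counts <- mixture_counts(ratio, total)
  parts <- vector("list", length(sources))
  frag_rows <- vector("list", length(sources))
  contribs <- vector("list", length(sources))
  for (k in seq_along(sources)) {
    src <- sources[[k]]
    pairs <- if (is.data.frame(src)) src else src$pairs
    manifest <- if (is.data.frame(src)) NULL else src$manifest
    if (counts[k] > nrow(pairs)) {
      stop_data("source %d has %d fragments, fewer than its share %d",
                k, nrow(pairs), counts[k])
    }
    sub <- subset_fastq(pairs, counts[k], derive_seed(seed, k))
    label <- if (!is.null(manifest)) manifest$contributors$label[1] else sprintf("source%d", k)
    hap <- if (!is.null(manifest)) manifest$contributors$haplogroup[1] else NA_character_
    if (length(sources) > 1L) sub$id <- paste0("s", k, "_", sub$id)
    parts[[k]] <- sub
    frag_rows[[k]] <- data.frame(id = sub$id, origin = label,
                                 stringsAsFactors = FALSE)
    contribs[[k]] <- data.frame(label = label, haplogroup = hap,
                                n_fragments = counts[k],
                                proportion = counts[k] / total,
                                stringsAsFactors = FALSE)
  }
  pairs <- as_read_pairs(do.call(rbind, parts))
  frags <- do.call(rbind, frag_rows)
  ord <- with_seed(derive_seed(seed, 0L), sample.int(nrow(pairs)))
  pairs <- as_read_pairs(pairs[ord, , drop = FALSE])
  frags <- frags[ord, , drop = FALSE]
  rownames(pairs) <- rownames(frags) <- NULL
  list(pairs = pairs,
       manifest = new_manifest(frags, do.call(rbind, contribs), seed = seed))
}

#' Spike NUMT-origin fragments into a mixture
#'
#' Adds `count` fragments sampled from the mito-derived segments of a
#' [build_numt_catalogue()], each read carrying 0-2 additional substitution
#' edits relative to the nuclear copy, and records their ids in the truth
#' manifest. Because the catalogue segments diverge from the mitogenome by
#' at least three edits per read-length window, these reads are the exact
#' set the NUMT filter should remove.
#'
#' @param mixture list with `pairs` and `manifest` (see [mix_fastqs()]).
#' @param catalogue a [build_numt_catalogue()].
#' @param count number of NUMT fragments to add.
#' @param per_read_edits integer vector to sample per-read edit counts from.
#' @param read_length,amplicon_mean,amplicon_sd,amplicon_range,quality as in
#'   [simulate_sole_source()].
#' @param seed generator seed.
#' @return the mixture with spiked pairs and updated manifest.
#' @export
spike_numts <- function(mixture, catalogue, count, per_read_edits = 0:2,
                        read_length = 150L, amplicon_mean = 167,
                        amplicon_sd = 15, amplicon_range = c(120L, 250L),
                        quality = 30L, seed = 1L) {
  if (count == 0L) return(mixture)
  with_seed(seed, {
    segs <- catalogue$segments
    pick <- sample.int(nrow(segs), count, replace = TRUE)
    lens <- as.integer(pmin(pmax(round(stats::rnorm(count, amplicon_mean, amplicon_sd)),
                                 amplicon_range[1]), amplicon_range[2]))
    frags <- character(count)
    for (i in seq_len(count)) {
      s <- segs[pick[i], ]
      maxstart <- s$seg_end - lens[i] + 1L
      st <- sample(s$seg_start:maxstart, 1L)
      frags[i] <- substr(catalogue$sequences[[s$name]], st, st + lens[i] - 1L)
    }
    r1len <- pmin(read_length, lens)
    seq1 <- substring(frags, 1L, r1len)
    seq2 <- revcomp(substring(frags, lens - r1len + 1L, lens))
    add_edits <- function(seqs) {
      k <- sample(per_read_edits, length(seqs), replace = TRUE)
      for (i in which(k > 0L)) {
        pos <- sample.int(nchar(seqs[i]), k[i])
        for (p in pos) {
          cur <- substr(seqs[i], p, p)
          substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
      }
      seqs
    }
    seq1 <- add_edits(seq1); seq2 <- add_edits(seq2)
    qual <- strrep(int_to_phred(quality), r1len)
    ids <- sprintf("numt_%06d", seq_len(count))
    spiked <- read_pairs(ids, seq1, qual, seq2, qual)
    pairs <- as_read_pairs(rbind(mixture$pairs, spiked))
    frags_df <- rbind(mixture$manifest$fragments[, c("id", "origin")],
                      data.frame(id = ids, origin = "NUMT",
                                 stringsAsFactors = FALSE))
    ord <- sample.int(nrow(pairs))
    pairs <- as_read_pairs(pairs[ord, , drop = FALSE])
    frags_df <- frags_df[ord, , drop = FALSE]
    rownames(pairs) <- rownames(frags_df) <- NULL
    manifest <- mixture$manifest
    manifest$fragments <- frags_df
    manifest$numt_ids <- c(manifest$numt_ids, ids)
    list(pairs = pairs, manifest = manifest)
  })
}

#' Randomly reduce a mixture to a target fragment count
#'
#' Without-replacement subsetting of a mixture (the deconvolution-side
#' analogue of reducing sequencing depth); the manifest's per-contributor
#' counts and proportions are recomputed for the retained fragments.
#'
#' @param mixture list with `pairs` and `manifest`.
#' @param k target fragment count.
#' @param seed selection seed.
#' @return reduced mixture with updated manifest.
#' @export
random_reduce <- function(mixture, k, seed = 1L) {
  pairs <- subset_fastq(mixture$pairs, k, seed)
  manifest <- mixture$manifest
  keep <- match(pairs$id, manifest$fragments$id)
  manifest$fragments <- manifest$fragments[keep, , drop = FALSE]
  rownames(manifest$fragments) <- NULL
  tab <- table(manifest$fragments$origin)
  ix <- match(manifest$contributors$label, names(tab))
  manifest$contributors$n_fragments <- ifelse(is.na(ix), 0L, as.integer(tab[ix]))
  mito_total <- sum(manifest$contributors$n_fragments)
  manifest$contributors$proportion <- manifest$contributors$n_fragments / mito_total
  manifest$numt_ids <- intersect(manifest$numt_ids, pairs$id)
  list(pairs = pairs, manifest = manifest)
}
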