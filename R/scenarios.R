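# Seeded validation studies on the bundled synthetic system. These drive
# both the test suite and the reproduction script: each study generates its
# mixtures from scratch, runs the pipeline, and scores against the truth
# manifest.

# Contributor pairs from different clades; checked to differ at >= 5
# haplogroup-defining SNPs.
well_separated_pairs <- function(tree) {
  pairs <- list(c("L0a1", "U5a"), c("M7a", "H1"), c("L0b", "B2"),
                c("M8a", "U5"), c("D4", "L0c"), c("L0a", "M7"),
                c("B2a", "L0c"), c("U5a", "M8"), c("H1", "L0b"),
                c("D4", "U5a"))
  for (p in pairs) {
    a <- expected_variants(tree, p[1]); b <- expected_variants(tree, p[2])
    ka <- paste0(a$position, a$derived); kb <- paste0(b$position, b$derived)
    stopifnot(length(setdiff(ka, kb)) + length(setdiff(kb, ka)) >= 5L)
  }
  pairs
}

# Simulate a mixture at exact per-contributor fragment counts and run it
# through preprocessing (optionally) and deconvolution.
run_synthetic_mixture <- function(haplogroups, counts, seed,
                                  tree, ref, primers = NULL, nuclear = NULL,
                                  preprocess = TRUE, ...) {
  sources <- lapply(seq_along(haplogroups), function(k) {
    simulate_sole_source(ref, tree, haplogroup = haplogroups[k],
                         n_fragments = counts[k],
                         seed = derive_seed(seed, k),
                         label = haplogroups[k])
  })
  mix <- mix_fastqs(sources, ratio = counts, total = sum(counts),
                    seed = derive_seed(seed, 100L))
  if (preprocess) {
    pre <- preprocess_pipeline(mix$pairs, primers, ref, nuclear)
    fragments <- merge_pairs(pre)
  } else {
    pre <- correct_pairs(mix$pairs)
    fragments <- merge_pairs(pre)
  }
  obs <- build_observations(fragments, tree, ref)
  res <- deconvolute(obs, tree, ...)
  list(result = res, manifest = mix$manifest, obs = obs)
}

#' Haplogroup detection study on two-person synthetic mixtures
#'
#' Generates seeded two-person amplicon mixtures with well-separated
#' contributor clades and minor contributions of 5-50%, runs the full
#' pipeline (preprocessing included), and scores a contributor as detected
#' when its exact haplogroup name is reported.
#'
#' @param seed study seed.
#' @param n_mixtures number of mixtures.
#' @param total_fragments fragments per mixture (20,000 corresponds to
#'   roughly 215x mitogenome coverage at 167-base amplicons).
#' @param minors minor-contribution fractions cycled over the mixtures.
#' @return list with `detail` (per-contributor data frame) and
#'   `pct_exact` (percentage of contributors exactly identified).
#' @export
detection_study <- function(seed = 1L, n_mixtures = 10L,
                            total_fragments = 20000L,
                            minors = c(0.05, 0.1, 0.25, 0.5)) {
  ref <- synthetic_reference()
  tree <- synthetic_phylotree(ref)
  primers <- synthetic_primer_set(ref)
  nuclear <- build_numt_catalogue(ref)$sequences
  pairs <- well_separated_pairs(tree)
  rows <- list()
  for (i in seq_len(n_mixtures)) {
    hg <- pairs[[(i - 1L) %% length(pairs) + 1L]]
    minor <- minors[(i - 1L) %% length(minors) + 1L]
    n_minor <- round(minor * total_fragments)
    counts <- c(total_fragments - n_minor, n_minor)
    run <- run_synthetic_mixture(hg, counts, derive_seed(seed, i),
                                 tree, ref, primers, nuclear)
    reported <- run$result$contributors$haplogroup
    rows[[i]] <- data.frame(mixture = i, haplogroup = hg,
                            true_proportion = counts / sum(counts),
                            detected = hg %in% reported,
                            stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, rows)
  list(detail = detail, pct_exact = 100 * mean(detail$detected))
}

#' Ratio-panel detection study (two- and three-person mixtures)
#'
#' One synthetic mixture per canonical ratio: 1:1, 1:3, 3:1 for two-person
#' and 1:1:1, 1:3:3, 3:3:1 for three-person mixtures. A contributor counts
#' as detected when the reported haplogroup is the true node, its parent,
#' or one of its children.
#'
#' @param seed study seed.
#' @param total_fragments fragments per mixture.
#' @return list with `detail` and `pct_detected`.
#' @export
ratio_panel_study <- function(seed = 1L, total_fragments = 20000L) {
  ref <- synthetic_reference()
  tree <- synthetic_phylotree(ref)
  primers <- synthetic_primer_set(ref)
  nuclear <- build_numt_catalogue(ref)$sequences
  panel <- list(
    list(hg = c("L0a1", "U5a"), ratio = c(1, 1)),
    list(hg = c("M7a", "H1"), ratio = c(1, 3)),
    list(hg = c("L0b", "B2"), ratio = c(3, 1)),
    list(hg = c("L0a1", "M7a", "U5a"), ratio = c(1, 1, 1)),
    list(hg = c("L0b", "M8a", "B2"), ratio = c(1, 3, 3)),
    list(hg = c("D4", "U5", "L0c"), ratio = c(3, 3, 1))
  )
  rows <- list()
  for (i in seq_along(panel)) {
    hg <- panel[[i]]$hg
    counts <- mixture_counts(panel[[i]]$ratio, total_fragments)
    run <- run_synthetic_mixture(hg, counts, derive_seed(seed, 200L + i),
                                 tree, ref, primers, nuclear)
    reported <- run$result$contributors$haplogroup
    hit <- vapply(hg, function(h) {
      accept <- c(h, haplogroup_parent(tree, h), haplogroup_children(tree, h))
      any(reported %in% accept)
    }, logical(1))
    rows[[i]] <- data.frame(mixture = i, haplogroup = hg,
                            ratio = paste(panel[[i]]$ratio, collapse = ":"),
                            true_proportion = counts / sum(counts),
                            detected = unname(hit), stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, rows)
  list(detail = detail, pct_detected = 100 * mean(detail$detected))
}

#' Proportion-recovery study on two-person synthetic mixtures
#'
#' Seeded two-person mixtures with minor fractions drawn uniformly from
#' 5-50% at fixed total depth; reports the mean absolute error between
#' estimated and true contributor proportions (an undetected contributor
#' contributes its full true proportion as error).
#'
#' @param seed study seed.
#' @param n_mixtures number of mixtures.
#' @param total_fragments fragments per mixture.
#' @return list with `detail` and `mean_abs_error`.
#' @export
proportion_study <- function(seed = 1L, n_mixtures = 20L,
                             total_fragments = 20000L) {
  ref <- synthetic_reference()
  tree <- synthetic_phylotree(ref)
  pairs <- well_separated_pairs(tree)
  minors <- with_seed(derive_seed(seed, 999L),
                      stats::runif(n_mixtures, 0.05, 0.5))
  rows <- list()
  for (i in seq_len(n_mixtures)) {
    hg <- pairs[[(i - 1L) %% length(pairs) + 1L]]
    n_minor <- round(minors[i] * total_fragments)
    counts <- c(total_fragments - n_minor, n_minor)
    run <- run_synthetic_mixture(hg, counts, derive_seed(seed, 300L + i),
                                 tree, ref, preprocess = FALSE)
    rep_df <- run$result$contributors
    err <- vapply(seq_along(hg), function(k) {
      true_p <- counts[k] / sum(counts)
      j <- match(hg[k], rep_df$haplogroup)
      if (is.na(j)) true_p else abs(rep_df$proportion[j] - true_p)
    }, numeric(1))
    rows[[i]] <- data.frame(mixture = i, haplogroup = hg,
                            true_proportion = counts / sum(counts),
                            abs_error = err, stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, rows)
  list(detail = detail, mean_abs_error = mean(detail$abs_error))
}
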