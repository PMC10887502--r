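# Contributor selection, known-haplotype augmentation, and diagnostic-SNP
# reporting on top of the EM fit.

# Collapse candidates with identical cumulative substitution sets; grafted
# knowns win over tree nodes with the same haplotype so the report carries
# the sample label.
dedupe_candidates <- function(tree, candidates) {
  sig <- vapply(candidates, function(h) variant_signature(tree, h), character(1))
  known <- vapply(candidates, function(h) isTRUE(tree$nodes[[h]]$known), logical(1))
  ord <- order(!known)           # knowns first, stable
  keep <- !duplicated(sig[ord])
  sort_back <- ord[keep]
  candidates[sort(sort_back)]
}

#' Select best-supported contributors from an EM state
#'
#' Iterative filtering: haplogroups with an estimated proportion below
#' `min_prop`, or with fewer than `min_unique_frags` fragments whose
#' responsibility for them exceeds 0.5, are discarded; EM is re-run
#' restricted to the survivors; the procedure repeats until the survivor set
#' is stable. Survivors are reported ranked by proportion (renormalized by
#' the final restricted fit) with the original full-candidate proportions
#' kept for bookkeeping. If every candidate is filtered, the single best
#' candidate is reported with a low-support warning flag.
#'
#' @param state an [em_fit()] state.
#' @param min_prop proportion floor. The default 0.005 sits below the 1-2%
#'   trace regime so that evidence counting, not the proportion floor,
#'   decides trace contributors.
#' @param min_unique_frags minimum fragments with responsibility > 0.5.
#' @param tol,max_iter passed to the restricted EM re-runs.
#' @return object of class `deconv_result` with `contributors` (data frame:
#'   `haplogroup`, `proportion`, `pi_full`, `n_unique_fragments`), the final
#'   `state`, `dropped` candidates, and a `low_support` flag.
#' @export
select_contributors <- function(state, min_prop = 0.005,
                                min_unique_frags = 10L,
                                tol = 1e-4, max_iter = 500L) {
  pi_full <- state$pi
  cur <- state
  for (round in 1:25) {
    unique_frags <- colSums(cur$resp > 0.5)
    keep <- cur$pi >= min_prop & unique_frags >= min_unique_frags
    if (!any(keep)) {
      top <- names(which.max(cur$pi))
      contributors <- data.frame(
        haplogroup = top, proportion = 1,
        pi_full = unname(pi_full[top]),
        n_unique_fragments = unname(unique_frags[top]),
        stringsAsFactors = FALSE)
      return(structure(list(contributors = contributors, state = cur,
                            dropped = setdiff(names(pi_full), top),
                            low_support = TRUE),
                       class = "deconv_result"))
    }
    if (all(keep)) break
    cur <- em_core(cur$L[, keep, drop = FALSE], tol, max_iter)
  }
  unique_frags <- colSums(cur$resp > 0.5)
  ord <- order(-cur$pi, names(cur$pi))
  contributors <- data.frame(
    haplogroup = names(cur$pi)[ord],
    proportion = unname(cur$pi[ord]),
    pi_full = unname(pi_full[names(cur$pi)[ord]]),
    n_unique_fragments = unname(unique_frags[ord]),
    stringsAsFactors = FALSE)
  structure(list(contributors = contributors, state = cur,
                 dropped = setdiff(names(pi_full), contributors$haplogroup),
                 low_support = FALSE),
            class = "deconv_result")
}

#' Deconvolute an observation matrix against a phylotree
#'
#' Runs [em_fit()] over the (deduplicated) candidate set, selects
#' best-supported contributors, and attaches the diagnostic-SNP report.
#'
#' @param obs an [build_observations()] matrix.
#' @param tree a `phylotree` with reference attached.
#' @param candidates candidate haplogroups (default: all tree nodes, with
#'   identical-haplotype duplicates collapsed). Pruning via
#'   [prune_candidates()] is applied automatically above
#'   `prune_above` candidates.
#' @param min_prop,min_unique_frags selection thresholds
#'   (see [select_contributors()]).
#' @param tol,max_iter EM controls.
#' @param prune_above candidate-count threshold above which the coarse
#'   pruning pass runs first.
#' @return a `deconv_result` with a `diagnostics` element
#'   (see [report_diagnostics()]).
#' @export
deconvolute <- function(obs, tree, candidates = NULL, min_prop = 0.005,
                        min_unique_frags = 10L, tol = 1e-4, max_iter = 500L,
                        prune_above = 200L) {
  candidates <- candidates %||% names(tree$nodes)
  candidates <- dedupe_candidates(tree, candidates)
  if (length(candidates) > prune_above) {
    candidates <- prune_candidates(obs, tree, candidates)
  }
  state <- em_fit(obs, tree, candidates, tol = tol, max_iter = max_iter)
  result <- select_contributors(state, min_prop, min_unique_frags, tol, max_iter)
  result$diagnostics <- report_diagnostics(result, obs, tree)
  result$tree <- tree
  result
}

#' Deconvolute with known contributor haplotypes in the candidate set
#'
#' Grafts each known haplotype into the tree (so the exact haplotypes,
#' including private mutations, compete with the tree haplogroups), rebuilds
#' the observation matrix so the knowns' private positions become
#' diagnostic, and re-runs deconvolution. Known-derived contributors are
#' labelled by their sample id in the report.
#'
#' @param obs an [build_observations()] matrix (its retained aligned
#'   fragments are reused to rebuild observations on the augmented tree).
#' @param tree a `phylotree`.
#' @param knowns list of [known_haplotype()] objects.
#' @param ... passed to [deconvolute()].
#' @return a `deconv_result`.
#' @export
deconvolute_with_knowns <- function(obs, tree, knowns, ...) {
  if (inherits(knowns, "known_haplotype")) knowns <- list(knowns)
  for (kh in knowns) tree <- graft_known_haplotype(tree, kh)
  obs2 <- build_observations(obs$fragments, tree, tree$reference)
  deconvolute(obs2, tree, ...)
}

#' Diagnostic-SNP report and partial haplotypes
#'
#' For each reported contributor, lists its expected diagnostic SNPs that
#' are covered in the data, with the fraction of covering fragments carrying
#' the derived allele. The partial haplotype is the subset of diagnostic
#' SNPs actually observed at a fraction consistent with the contributor's
#' proportion (at least half of it, and at least 2 supporting fragments).
#' Contributors whose support rests on one or two diagnostic positions are
#' flagged (`few_snp_support`): the signature of a spurious haplogroup
#' arising from a private mutation or heteroplasmy. A contributor none of
#' whose expected SNPs are covered gets a `no_coverage` flag.
#'
#' @param result a [select_contributors()] result.
#' @param obs the [build_observations()] matrix used for the fit.
#' @param tree the `phylotree` used for the fit.
#' @return named list (one entry per contributor) with elements `snps`
#'   (data frame: position, expected allele, observed fraction, covering
#'   fragments, derived count), `partial_haplotype` (character tokens),
#'   `no_coverage`, `few_snp_support`.
#' @export
report_diagnostics <- function(result, obs, tree) {
  out <- list()
  o <- obs$obs
  # expected variant keys per reported contributor, to separate a
  # contributor's unique support from backbone variants shared with other
  # reported contributors
  all_keys <- lapply(result$contributors$haplogroup, function(h) {
    v <- expected_variants(tree, h)
    v <- v[v$kind == "substitution", , drop = FALSE]
    paste0(v$position, v$derived)
  })
  names(all_keys) <- result$contributors$haplogroup
  for (i in seq_len(nrow(result$contributors))) {
    h <- result$contributors$haplogroup[i]
    prop <- result$contributors$proportion[i]
    v <- expected_variants(tree, h)
    v <- v[v$kind == "substitution", , drop = FALSE]
    if (nrow(v)) {
      n_cov <- integer(nrow(v)); n_der <- integer(nrow(v))
      for (j in seq_len(nrow(v))) {
        at <- o$position == v$position[j]
        n_cov[j] <- sum(at)
        n_der[j] <- sum(o$base[at] == v$derived[j])
      }
      snps <- data.frame(position = v$position,
                         expected_allele = v$derived,
                         observed_fraction = ifelse(n_cov > 0, n_der / n_cov, NA_real_),
                         n_covering = n_cov, n_derived = n_der,
                         stringsAsFactors = FALSE)
    } else {
      snps <- data.frame(position = integer(0), expected_allele = character(0),
                         observed_fraction = numeric(0),
                         n_covering = integer(0), n_derived = integer(0))
    }
    observed <- snps$n_covering > 0 & snps$n_derived >= 2 &
      snps$observed_fraction >= pmax(0.5 * prop, 0.02)
    partial <- paste0(snps$position[observed], snps$expected_allele[observed])
    shared <- unlist(all_keys[names(all_keys) != h], use.names = FALSE)
    unique_snp <- !(paste0(snps$position, snps$expected_allele) %in% shared)
    out[[h]] <- list(
      snps = snps,
      partial_haplotype = partial,
      no_coverage = nrow(snps) > 0 && all(snps$n_covering == 0),
      few_snp_support = sum(observed & unique_snp) <= 2
    )
  }
  out
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("<deconv_result> %d contributor(s)%s\n",
              nrow(x$contributors),
              if (isTRUE(x$low_support)) " [low support]" else ""))
  df <- x$contributors
  for (i in seq_len(nrow(df))) {
    extra <- ""
    if (!is.null(x$diagnostics)) {
      d <- x$diagnostics[[df$haplogroup[i]]]
      if (!is.null(d)) {
        extra <- sprintf("  [%d diagnostic SNPs%s]",
                         length(d$partial_haplotype),
                         if (d$few_snp_support) ", few-SNP support" else "")
      }
    }
    cat(sprintf("  %-14s %6.3f%s\n", df$haplogroup[i], df$proportion[i], extra))
  }
  invisible(x)
}
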