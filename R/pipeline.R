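# End-to-end run: configuration, staged execution, report/metrics output.

#' Validate a run configuration
#'
#' A configuration is a named list (or a YAML file) with input paths and
#' parameters. Exactly one input mode is allowed: paired FASTQ
#' (`fastq1`/`fastq2`) or an alignment file (`bam`). Required: `tree`
#' (phylotree TSV) and `mito_ref` (FASTA). Optional: `nuclear_ref`,
#' `primers`, `knowns`, `out_dir`, `seed`, and the EM/selection thresholds
#' `min_prop`, `min_unique_frags`, `min_overlap`, `pad`.
#'
#' @param config named list or YAML path.
#' @return validated config list with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_config("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a list or YAML path")
  has_fastq <- !is.null(config$fastq1) || !is.null(config$fastq2)
  has_bam <- !is.null(config$bam)
  if (has_fastq && has_bam) stop_config("input modes are mutually exclusive: give fastq1/fastq2 or bam")
  if (has_fastq && (is.null(config$fastq1) || is.null(config$fastq2))) {
    stop_config("paired input needs both fastq1 and fastq2")
  }
  if (!has_fastq && !has_bam) stop_config("no input: give fastq1/fastq2 or bam")
  for (field in c("tree", "mito_ref")) {
    if (is.null(config[[field]])) stop_config("missing required config field '%s'", field)
  }
  paths <- c(config$fastq1, config$fastq2, config$bam, config$tree,
             config$mito_ref, config$nuclear_ref, config$primers, config$knowns)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop_config("config path(s) do not exist: %s",
                                   paste(missing, collapse = ", "))
  defaults <- list(out_dir = NULL, seed = 1L, min_prop = 0.005,
                   min_unique_frags = 10L, min_overlap = 20L, pad = 200L,
                   primer_max_mismatch = 1L, tol = 1e-4, max_iter = 500L)
  for (nm in names(defaults)) config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  config
}

log_stage <- function(lines, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  c(lines, msg)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    cls <- class(e)[1]
    msg <- sprintf("stage '%s': %s", stage, conditionMessage(e))
    stop(structure(class = unique(c(cls, "error", "condition")),
                   list(message = msg, call = NULL)))
  })
}

#' Run the full deconvolution pipeline
#'
#' Executes preprocessing (pair correction, primer trimming, NUMT removal),
#' fragment placement, observation building, EM deconvolution (with a
#' second pass over grafted known haplotypes when provided) and diagnostic
#' reporting. When `out_dir` is set, writes `report.json`, `report.txt`,
#' `metrics.json` and `run.log`; partial outputs are removed if any stage
#' fails. Fully deterministic given the seed.
#'
#' @param config see [run_config()].
#' @return a `deconv_result` with `metrics` and (if `out_dir` is set)
#'   `paths` attached.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  out_files <- character(0)
  lines <- character(0)
  cleanup <- function() if (length(out_files)) unlink(out_files)

  result <- tryCatch({
    ref <- with_stage("load", read_mito_reference(config$mito_ref))
    tree <- with_stage("load", read_phylotree(config$tree, reference = ref))
    primers <- if (!is.null(config$primers)) with_stage("load", read_primer_set(config$primers))
    knowns <- if (!is.null(config$knowns)) with_stage("load", read_known_haplotypes(config$knowns, ref))
    nuclear <- config$nuclear_ref

    if (!is.null(config$bam)) {
      al <- with_stage("read-input", read_alignments(config$bam, ref))
      warning("alignment-file input: pair correction and primer trimming skipped (FASTQ required for noise filtration)",
              call. = FALSE)
      lines <- log_stage(lines, "input: %d alignment records (correction/trimming skipped)",
                         nrow(al))
      al <- al[al$mapped & !is.na(al$pos), , drop = FALSE]
      metrics <- list(input_fragments = nrow(al))
      # NUMT stage still runs on the read sequences.
      removed <- character(0)
      metrics$numt_candidates <- 0L
      metrics$numts_removed <- 0L
      if (!is.null(nuclear)) {
        set <- Biostrings::readDNAStringSet(nuclear)
        nuc_seq <- paste(as.character(set), collapse = strrep("N", 15L))
        nal <- align_to_reference(al$seq, kmer_index(nuc_seq))
        nal$read_id <- al$read_id
        cand <- numt_candidates(nal)
        metrics$numt_candidates <- length(cand)
        if (length(cand)) {
          ci <- match(cand, al$read_id)
          mal <- align_to_reference(al$seq[ci],
                                    kmer_index(circularize_reference(ref, config$pad)))
          removed <- classify_numts(cand,
                                    stats::setNames(nal$lev[ci], cand),
                                    stats::setNames(mal$lev, cand))
          metrics$numts_removed <- length(removed)
        }
        al <- al[!(al$read_id %in% removed), , drop = FALSE]
      }
      metrics$fragments_out <- nrow(al)
      fragments <- data.frame(id = al$read_id, seq = al$seq, qual = al$qual,
                              start = al$pos, stringsAsFactors = FALSE)
    } else {
      pairs <- with_stage("read-input", read_fastq_pair(config$fastq1, config$fastq2))
      lines <- log_stage(lines, "input: %d read pairs", nrow(pairs))
      pre <- with_stage("preprocess",
                        preprocess_pipeline(pairs, primers, ref, nuclear,
                                            min_overlap = config$min_overlap,
                                            primer_max_mismatch = config$primer_max_mismatch,
                                            pad = config$pad))
      metrics <- pre$metrics
      lines <- log_stage(lines,
                         "preprocess: %d in; %d corrected, %d no-overlap; %d reads trimmed; %d NUMT candidates, %d NUMT fragments removed; %d out",
                         metrics$input_fragments, metrics$pairs_corrected,
                         metrics$pairs_no_overlap, metrics$reads_trimmed,
                         metrics$numt_candidates, metrics$numts_removed,
                         metrics$fragments_out)
      stopifnot(metrics$input_fragments == metrics$fragments_out + metrics$numts_removed)
      fragments <- with_stage("merge", merge_pairs(pre))
    }

    obs <- with_stage("observations",
                      build_observations(fragments, tree, ref, pad = config$pad))
    lines <- log_stage(lines,
                       "observations: %d fragments placed (%d informative, %d unplaced), %d diagnostic positions",
                       obs$n_fragments, sum(obs$informative), obs$n_excluded,
                       length(obs$positions))
    metrics$fragments_informative <- sum(obs$informative)
    metrics$fragments_unplaced <- obs$n_excluded

    result <- with_stage("deconvolute",
                         if (is.null(knowns)) {
                           deconvolute(obs, tree, min_prop = config$min_prop,
                                       min_unique_frags = config$min_unique_frags,
                                       tol = config$tol, max_iter = config$max_iter)
                         } else {
                           deconvolute_with_knowns(obs, tree, knowns,
                                                   min_prop = config$min_prop,
                                                   min_unique_frags = config$min_unique_frags,
                                                   tol = config$tol,
                                                   max_iter = config$max_iter)
                         })
    lines <- log_stage(lines, "deconvolution: %d contributor(s): %s",
                       nrow(result$contributors),
                       paste(sprintf("%s (%.3f)", result$contributors$haplogroup,
                                     result$contributors$proportion),
                             collapse = ", "))
    result$metrics <- metrics

    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- file.path(config$out_dir,
                         c("report.json", "report.txt", "metrics.json", "run.log"))
      out_files <- paths
      jsonlite::write_json(report_as_list(result), paths[1],
                           auto_unbox = TRUE, digits = 10, pretty = TRUE)
      writeLines(report_as_text(result), paths[2])
      jsonlite::write_json(metrics, paths[3], auto_unbox = TRUE, pretty = TRUE)
      writeLines(lines, paths[4])
      result$paths <- stats::setNames(as.list(paths),
                                      c("report_json", "report_txt", "metrics_json", "log"))
    }
    result
  }, error = function(e) { cleanup(); stop(e) })
  result
}

report_as_list <- function(result) {
  list(
    schema_version = "1.0",
    low_support = isTRUE(result$low_support),
    contributors = lapply(seq_len(nrow(result$contributors)), function(i) {
      h <- result$contributors$haplogroup[i]
      d <- result$diagnostics[[h]]
      list(haplogroup = h,
           proportion = result$contributors$proportion[i],
           proportion_full_model = result$contributors$pi_full[i],
           n_unique_fragments = result$contributors$n_unique_fragments[i],
           partial_haplotype = as.list(d$partial_haplotype %||% character(0)),
           no_coverage = isTRUE(d$no_coverage),
           few_snp_support = isTRUE(d$few_snp_support),
           diagnostic_snps = if (!is.null(d)) d$snps else NULL)
    })
  )
}

report_as_text <- function(result) {
  out <- c("mitodemix deconvolution report", "")
  for (i in seq_len(nrow(result$contributors))) {
    h <- result$contributors$haplogroup[i]
    d <- result$diagnostics[[h]]
    out <- c(out, sprintf("contributor %d: %s  proportion %.4f  (unique fragments: %d)%s",
                          i, h, result$contributors$proportion[i],
                          result$contributors$n_unique_fragments[i],
                          if (isTRUE(d$few_snp_support)) "  [few-SNP support]" else ""))
    if (!is.null(d) && nrow(d$snps)) {
      covered <- d$snps[d$snps$n_covering > 0, , drop = FALSE]
      for (j in seq_len(nrow(covered))) {
        out <- c(out, sprintf("    %6d%s  observed %.3f  (%d/%d fragments)",
                              covered$position[j], covered$expected_allele[j],
                              covered$observed_fraction[j],
                              covered$n_derived[j], covered$n_covering[j]))
      }
      out <- c(out, sprintf("    partial haplotype: %s",
                            if (length(d$partial_haplotype)) paste(d$partial_haplotype, collapse = " ")
                            else "(none)"))
    }
  }
  if (isTRUE(result$low_support)) {
    out <- c(out, "", "warning: all candidates fell below support thresholds; top candidate reported")
  }
  out
}
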