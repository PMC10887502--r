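# Haplogroup phylotree: variant token grammar, tree parsing, cumulative
# expected haplotypes, similarity, and grafting of known haplotypes.
#
# The tree input format is a plain TSV dialect (the upstream mtDNA phylogeny
# is distributed as HTML/Excel, so a converter is left to the user): one node
# per line, depth encoded as leading tab indentation, then the haplogroup
# name, then space-separated variant tokens. A "!" suffix marks a back
# mutation (reversion to the ancestral allele), following the usual phylotree
# convention.

empty_variants <- function() {
  data.frame(position = integer(0), ref = character(0),
             derived = character(0), kind = character(0),
             back_mutation = logical(0), stringsAsFactors = FALSE)
}

#' Parse a single variant token
#'
#' Tokens follow mtDNA phylogeny notation: `"16093C"` (substitution to C at
#' 16093, optionally written `"T16093C"` with the ancestral base),
#' `"249d"` (deletion), `"573.1C"` (insertion after 573), and a `"!"`
#' suffix for back mutations.
#'
#' @param token variant token string.
#' @param reference optional [mito_reference()] used to fill in (and check)
#'   the reference allele.
#' @return one-row data frame with columns `position`, `ref`, `derived`,
#'   `kind`, `back_mutation`.
#' @export
#' @examples
#' parse_variant_token("16093C")
parse_variant_token <- function(token, reference = NULL) {
  raw <- token
  back <- grepl("!$", token)
  token <- sub("!+$", "", token)
  m <- regmatches(token, regexec(
    "^([ACGTacgt])?([0-9]+)(?:(d)|\\.([0-9]+)([ACGTacgt]+)|([ACGTacgt]))$",
    token))[[1]]
  if (!length(m)) stop_data("malformed variant token: '%s'", raw)
  pos <- as.integer(m[3])
  lead_ref <- toupper(m[2])
  if (nzchar(m[4])) {
    kind <- "deletion"; derived <- "-"
  } else if (nzchar(m[6])) {
    kind <- "insertion"; derived <- paste0(".", m[5], toupper(m[6]))
  } else {
    kind <- "substitution"; derived <- toupper(m[7])
  }
  ref <- NA_character_
  if (!is.null(reference)) {
    if (pos < 1L || pos > reference$length) {
      stop_data("variant position %d outside reference of length %d",
                pos, reference$length)
    }
    if (kind %in% c("substitution", "deletion")) {
      ref <- substr(reference$sequence, pos, pos)
      if (nzchar(lead_ref) && lead_ref != ref) {
        stop_data("token '%s': stated reference allele %s differs from reference base %s",
                  raw, lead_ref, ref)
      }
    }
  } else if (nzchar(lead_ref)) {
    ref <- lead_ref
  }
  data.frame(position = pos, ref = ref, derived = derived, kind = kind,
             back_mutation = back, stringsAsFactors = FALSE)
}

parse_variant_tokens <- function(tokens, reference = NULL) {
  if (!length(tokens)) return(empty_variants())
  do.call(rbind, lapply(tokens, parse_variant_token, reference = reference))
}

#' Parse a haplogroup phylotree from its TSV dialect
#'
#' @param text character vector of lines, or a single string with embedded
#'   newlines. Blank lines and lines starting with `#` are ignored.
#' @param reference optional [mito_reference()]; when given, variant
#'   reference alleles are resolved and positions validated.
#' @return an object of class `phylotree`: a named list of nodes (each with
#'   `name`, `parent`, `variants`, `known`), plus the reference.
#' @export
#' @examples
#' txt <- c("mt-MRCA", "\tH\t2706A 7028C", "\t\tH1\t3010A")
#' tree <- parse_phylotree(txt)
#' names(tree$nodes)
parse_phylotree <- function(text, reference = NULL) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text <- sub("\r$", "", text)
  keep <- nzchar(trimws(text)) & !grepl("^\\s*#", text)
  lines <- text[keep]
  lineno <- which(keep)
  if (!length(lines)) stop_data("phylotree parse error: no node lines in input")

  nodes <- list()
  order <- character(0)
  stack <- character(0)  # stack[d] = name of last node at depth d-1
  for (i in seq_along(lines)) {
    ln <- lines[i]
    depth <- nchar(ln) - nchar(sub("^\t+", "", ln))
    body <- trimws(sub("^\t+", "", ln))
    fields <- strsplit(body, "[ \t]+")[[1]]
    name <- fields[1]
    tokens <- fields[-1]
    if (!nzchar(name)) {
      stop_data("phylotree parse error at line %d: missing node name", lineno[i])
    }
    if (name %in% names(nodes)) {
      stop_data("phylotree parse error at line %d: duplicate node name '%s'",
                lineno[i], name)
    }
    if (i == 1L && depth != 0L) {
      stop_data("phylotree parse error at line %d: first node must be the root (no indent)",
                lineno[i])
    }
    if (i > 1L && depth == 0L) {
      stop_data("phylotree parse error at line %d: second root '%s' (exactly one root allowed)",
                lineno[i], name)
    }
    if (depth > length(stack)) {
      stop_data("phylotree parse error at line %d: node '%s' indented %d levels but has no parent at level %d",
                lineno[i], name, depth, depth - 1L)
    }
    parent <- if (depth == 0L) NA_character_ else stack[depth]
    variants <- tryCatch(
      parse_variant_tokens(tokens, reference),
      error = function(e) {
        stop_data("phylotree parse error at line %d: %s", lineno[i],
                  conditionMessage(e))
      }
    )
    nodes[[name]] <- list(name = name, parent = parent, variants = variants,
                          known = FALSE)
    order <- c(order, name)
    stack <- c(stack[seq_len(depth)], name)
  }
  structure(list(nodes = nodes, order = order, reference = reference),
            class = "phylotree")
}

#' Read a phylotree from a TSV file
#' @param path file in the documented TSV dialect.
#' @param reference optional [mito_reference()].
#' @return a `phylotree`.
#' @export
read_phylotree <- function(path, reference = NULL) {
  if (!file.exists(path)) stop_config("phylotree file not found: %s", path)
  parse_phylotree(readLines(path, warn = FALSE), reference = reference)
}

#' Write a phylotree to the TSV dialect
#' @param tree a `phylotree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylotree <- function(tree, path) {
  depth_of <- function(name) {
    d <- 0L
    p <- tree$nodes[[name]]$parent
    while (!is.na(p)) { d <- d + 1L; p <- tree$nodes[[p]]$parent }
    d
  }
  fmt_tok <- function(v) {
    tok <- switch(v$kind,
      substitution = paste0(v$position, v$derived),
      deletion = paste0(v$position, "d"),
      insertion = paste0(v$position, v$derived))
    if (v$back_mutation) tok <- paste0(tok, "!")
    tok
  }
  lines <- vapply(tree$order, function(nm) {
    node <- tree$nodes[[nm]]
    toks <- if (nrow(node$variants)) {
      paste(vapply(seq_len(nrow(node$variants)),
                   function(i) fmt_tok(node$variants[i, ]), character(1)),
            collapse = " ")
    } else ""
    paste0(strrep("\t", depth_of(nm)), nm,
           if (nzchar(toks)) paste0("\t", toks) else "")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.phylotree <- function(x, ...) {
  cat(sprintf("<phylotree> %d haplogroups, root '%s'%s\n",
              length(x$nodes), x$order[1],
              if (!is.null(x$reference)) sprintf(", reference %s (%d bp)",
                                                 x$reference$name,
                                                 x$reference$length) else ""))
  invisible(x)
}

root_name <- function(tree) tree$order[1]

path_to_root <- function(tree, haplogroup) {
  if (is.null(tree$nodes[[haplogroup]])) {
    stop_data("unknown haplogroup '%s'", haplogroup)
  }
  path <- character(0)
  nm <- haplogroup
  while (!is.na(nm)) {
    path <- c(nm, path)
    nm <- tree$nodes[[nm]]$parent
  }
  path
}

#' Cumulative expected variants of a haplogroup
#'
#' Walks the root-to-node path and accumulates defining variants. A back
#' mutation removes the earlier variant at its position; a later assignment
#' at an already-seen position overrides the earlier one.
#'
#' @param tree a `phylotree`.
#' @param haplogroup haplogroup name present in the tree.
#' @return variant data frame (see [parse_variant_token()]) sorted by
#'   position; zero rows for the root.
#' @export
expected_variants <- function(tree, haplogroup) {
  path <- path_to_root(tree, haplogroup)
  acc <- list()
  for (nm in path) {
    v <- tree$nodes[[nm]]$variants
    for (i in seq_len(nrow(v))) {
      key <- as.character(v$position[i])
      if (v$back_mutation[i]) {
        acc[[key]] <- NULL
      } else {
        acc[[key]] <- v[i, , drop = FALSE]
      }
    }
  }
  if (!length(acc)) return(empty_variants())
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}

#' All phylogenetically diagnostic positions of a tree
#'
#' @param tree a `phylotree`.
#' @return sorted integer vector of distinct positions appearing in any
#'   node's defining variants.
#' @export
diagnostic_positions <- function(tree) {
  pos <- unlist(lapply(tree$nodes, function(n) n$variants$position),
                use.names = FALSE)
  sort(unique(as.integer(pos)))
}

#' Percent shared haplogroup-defining SNPs between two variant sets
#'
#' Similarity between two cumulative haplotypes, as a percentage. Variants
#' match exactly on position plus derived allele. The default denominator is
#' the union (Jaccard); `method = "min"` divides by the smaller set instead.
#' Returns 0 when the union (or smaller set) is empty.
#'
#' @param a,b variant data frames from [expected_variants()].
#' @param method `"jaccard"` (default) or `"min"`.
#' @return percentage in `[0, 100]`.
#' @export
#' @examples
#' tree <- parse_phylotree(c("root", "\tA\t73G 263G 750G", "\tB\t263G 750G 1438G"))
#' shared_diagnostic_fraction(expected_variants(tree, "A"),
#'                            expected_variants(tree, "B"))  # 50
shared_diagnostic_fraction <- function(a, b, method = c("jaccard", "min")) {
  method <- match.arg(method)
  vkey <- function(v) {
    if (is.null(v) || !nrow(v)) return(character(0))
    unique(paste0(v$position, ":", v$derived))
  }
  ka <- vkey(a)
  kb <- vkey(b)
  inter <- length(intersect(ka, kb))
  denom <- switch(method,
                  jaccard = length(union(ka, kb)),
                  min = min(length(ka), length(kb)))
  if (denom == 0L) return(0)
  100 * inter / denom
}

#' Construct a known contributor haplotype
#'
#' @param sample_id label for the contributor.
#' @param variants variant data frame (full differences from the reference),
#'   or a character vector of variant tokens.
#' @param heteroplasmies optional data frame with columns `position`,
#'   `minor_allele`, `maf` (minor allele frequency in `(0, 0.5]`).
#' @param reference optional [mito_reference()] for token resolution.
#' @return object of class `known_haplotype`.
#' @export
known_haplotype <- function(sample_id, variants, heteroplasmies = NULL,
                            reference = NULL) {
  if (is.character(variants)) {
    variants <- parse_variant_tokens(variants, reference)
  }
  if (anyDuplicated(variants$position)) {
    stop_data("known haplotype '%s': duplicate variant positions", sample_id)
  }
  if (!is.null(heteroplasmies) && nrow(heteroplasmies)) {
    if (any(heteroplasmies$maf <= 0 | heteroplasmies$maf > 0.5)) {
      stop_config("heteroplasmy MAF must lie in (0, 0.5]")
    }
  }
  structure(list(sample_id = sample_id, variants = variants,
                 heteroplasmies = heteroplasmies),
            class = "known_haplotype")
}

#' Read known haplotypes from a TSV file
#'
#' One haplotype per line: `sample_id<TAB>token token ...`.
#'
#' @param path input file.
#' @param reference optional [mito_reference()].
#' @return list of [known_haplotype()] objects.
#' @export
read_known_haplotypes <- function(path, reference = NULL) {
  if (!file.exists(path)) stop_config("known-haplotype file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  lapply(lines, function(ln) {
    fields <- strsplit(trimws(ln), "[ \t]+")[[1]]
    known_haplotype(fields[1], fields[-1], reference = reference)
  })
}

#' Graft a known haplotype into a phylotree
#'
#' Adds a leaf named after the sample under the root whose cumulative
#' expected variants equal the known haplotype exactly, so the exact
#' haplotype competes with tree haplogroups during deconvolution. Existing
#' nodes are never modified.
#'
#' @param tree a `phylotree`.
#' @param kh a [known_haplotype()].
#' @return a new `phylotree` containing the extra leaf.
#' @export
graft_known_haplotype <- function(tree, kh) {
  stopifnot(inherits(kh, "known_haplotype"))
  if (kh$sample_id %in% names(tree$nodes)) {
    stop_data("known haplotype id '%s' collides with an existing haplogroup",
              kh$sample_id)
  }
  if (!is.null(tree$reference) && nrow(kh$variants)) {
    if (any(kh$variants$position < 1L |
            kh$variants$position > tree$reference$length)) {
      stop_data("known haplotype '%s': variant position outside reference",
                kh$sample_id)
    }
  }
  root <- root_name(tree)
  root_cum <- expected_variants(tree, root)
  defining <- kh$variants
  # Cancel any root-level variants the known haplotype does not carry, so the
  # cumulative set equals the haplotype exactly.
  stale <- root_cum[!(root_cum$position %in% defining$position), , drop = FALSE]
  if (nrow(stale)) {
    stale$back_mutation <- TRUE
    defining <- rbind(defining, stale)
  }
  tree$nodes[[kh$sample_id]] <- list(name = kh$sample_id, parent = root,
                                     variants = defining, known = TRUE)
  tree$order <- c(tree$order, kh$sample_id)
  tree
}

#' Parent of a haplogroup
#' @param tree a `phylotree`.
#' @param haplogroup node name.
#' @return parent name, or `NA` for the root.
#' @export
haplogroup_parent <- function(tree, haplogroup) {
  if (is.null(tree$nodes[[haplogroup]])) stop_data("unknown haplogroup '%s'", haplogroup)
  tree$nodes[[haplogroup]]$parent
}

#' Children of a haplogroup
#' @param tree a `phylotree`.
#' @param haplogroup node name.
#' @return character vector of child names.
#' @export
haplogroup_children <- function(tree, haplogroup) {
  if (is.null(tree$nodes[[haplogroup]])) stop_data("unknown haplogroup '%s'", haplogroup)
  names(Filter(function(n) identical(n$parent, haplogroup), tree$nodes))
}

# Signature of a node's cumulative substitution set, used to collapse
# duplicate candidates (e.g. a grafted known identical to a tree node).
variant_signature <- function(tree, haplogroup) {
  v <- expected_variants(tree, haplogroup)
  v <- v[v$kind == "substitution", , drop = FALSE]
  paste(paste0(v$position, v$derived), collapse = ";")
}
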