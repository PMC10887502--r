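# Internal helpers: seeded evaluation, condition classes, sequence utilities.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream. All randomised operations in this package route their
#' `seed` argument through this helper, which is what makes identical
#' config + seed produce byte-identical output.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_config("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

# Derive a child seed from a base seed; keeps results < 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% (.Machine$integer.max - 1)) + 1L
}

#' @keywords internal
stop_config <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(class = c("mitodemix_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @keywords internal
stop_data <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(class = c("mitodemix_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Reverse-complement a character vector of DNA strings.
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reverse each string in a character vector (for quality strings).
str_reverse <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Phred+33 helpers ------------------------------------------------------------

# Quality characters -> integer scores, for one string.
phred_to_int <- function(qual) {
  if (!nzchar(qual)) return(integer(0))
  as.integer(charToRaw(qual)) - 33L
}

# Integer score -> single quality character.
int_to_phred <- function(q) {
  intToUtf8(pmin(pmax(q, 0L), 93L) + 33L, multiple = FALSE)
}

# Vector of single quality characters -> error probabilities.
# Epsilon is capped below 1 so that log(1 - eps) stays finite.
phred_chars_to_eps <- function(chars) {
  q <- as.integer(charToRaw(paste(chars, collapse = ""))) - 33L
  pmin(10^(-q / 10), 0.75)
}

# Positions (vectorised) where two equal-length strings differ.
string_mismatches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  which(ra != rb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
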