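# Internal sequence helpers. Sequences are plain upper-case character
# scalars over {A,C,G,T,N} (alignments may also contain "-"); Biostrings
# objects are accepted at the boundaries and converted.

#' Normalise a nucleotide sequence string
#'
#' Upper-cases, converts RNA U to T, and validates the alphabet.
#'
#' @param x character scalar (or Biostrings XString) nucleotide sequence.
#' @param allow_gap allow the alignment gap character `-`.
#' @return normalised character scalar.
#' @keywords internal
#' @noRd
norm_seq <- function(x, allow_gap = FALSE) {
  if (inherits(x, "XString") || inherits(x, "XStringSet")) {
    x <- as.character(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  alphabet <- if (allow_gap) "ACGTN-" else "ACGTN"
  bad <- gsub(sprintf("[%s]", alphabet), "", x)
  if (nchar(bad) > 0L) {
    abort(sprintf(
      "sequence contains characters outside {%s}: %s",
      paste(strsplit(alphabet, "")[[1]], collapse = ","),
      paste(unique(strsplit(bad, "")[[1]]), collapse = " ")
    ))
  }
  x
}

# reverse complement of a character scalar (gap-aware)
revcomp <- function(x) {
  x <- chartr("ACGTN", "TGCAN", x)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

# split a sequence into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# split an in-frame sequence into complete codons (trailing partial dropped)
seq_codons <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# sample `n` bases from named base fractions (names A,T,G,C summing ~ 1)
sample_bases <- function(n, fractions) {
  sample(names(fractions), n, replace = TRUE, prob = fractions)
}
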