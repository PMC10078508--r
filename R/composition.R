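# Base composition and strand-skew statistics. Skews follow the standard
# strand-asymmetry definitions AT-skew = (A - T)/(A + T) and
# GC-skew = (G - C)/(G + C), computed on whichever strand a class is
# reported on (see class_composition for the conventions).

#' Base composition and skews of a sequence
#'
#' N bases are counted but excluded from percentages and skew
#' denominators; a zero skew denominator yields `NA`.
#'
#' @param seq nucleotide string (character or Biostrings object).
#' @return one-row tibble: counts `n_a/n_t/n_g/n_c/n_n`, percentages
#'   `a_pct/t_pct/g_pct/c_pct` (of non-N bases), `at_content`, `at_skew`,
#'   `gc_skew`, `length`.
#' @examples
#' composition_profile("AAAT") # at_skew = 0.5
#' @export
composition_profile <- function(seq) {
  seq <- norm_seq(seq)
  if (nchar(seq) == 0L) abort("empty sequence")
  counts <- table(factor(seq_chars(seq), levels = c("A", "T", "G", "C", "N")))
  n <- sum(counts[c("A", "T", "G", "C")])
  pct <- if (n > 0) 100 * counts / n else
    setNames(rep(NA_real_, 5), names(counts))
  sk <- skew_from_fractions(pct[["A"]], pct[["T"]], pct[["G"]], pct[["C"]])
  tibble(
    n_a = counts[["A"]], n_t = counts[["T"]],
    n_g = counts[["G"]], n_c = counts[["C"]], n_n = counts[["N"]],
    a_pct = pct[["A"]], t_pct = pct[["T"]],
    g_pct = pct[["G"]], c_pct = pct[["C"]],
    at_content = pct[["A"]] + pct[["T"]],
    at_skew = sk$at_skew, gc_skew = sk$gc_skew,
    length = nchar(seq)
  )
}

#' Strand skews from base fractions
#'
#' `AT-skew = (A - T)/(A + T)`, `GC-skew = (G - C)/(G + C)`. Works on
#' percentages or proportions alike (the scale cancels).
#'
#' @param a_pct,t_pct,g_pct,c_pct non-negative base fractions.
#' @return one-row tibble with `at_skew` and `gc_skew` at full precision
#'   (round for display; mitogenome papers print 2 decimals). A zero
#'   denominator gives `NA`.
#' @examples
#' skew_from_fractions(41.8, 24.9, 12.3, 21.0) # 0.25, -0.26 at 2 dp
#' @export
skew_from_fractions <- function(a_pct, t_pct, g_pct, c_pct) {
  vals <- c(a_pct, t_pct, g_pct, c_pct)
  if (anyNA(vals) || any(vals < 0)) {
    return(tibble(at_skew = NA_real_, gc_skew = NA_real_))
  }
  tibble(
    at_skew = if (a_pct + t_pct > 0) (a_pct - t_pct) / (a_pct + t_pct) else NA_real_,
    gc_skew = if (g_pct + c_pct > 0) (g_pct - c_pct) / (g_pct + c_pct) else NA_real_
  )
}

# concatenated sense-strand sequence of a feature class; codon position
# classes pull complete codons (terminal stop excluded) from all PCGs
class_sequence <- function(x, class, code_id = 5) {
  stopifnot(inherits(x, "mitogenome"))
  if (is.null(x$sequence)) abort("sequence required")
  f <- x$features
  if (class == "genome") return(x$sequence)
  if (class %in% c("PCG", "tRNA", "rRNA", "control")) {
    genes <- f$name[f$category == class]
    if (!length(genes)) abort(sprintf("record has no %s features", class))
    return(paste(vapply(genes, function(g) feature_sequence(x, g),
                        character(1)), collapse = ""))
  }
  if (grepl("^codon_pos_[123]$", class)) {
    pos <- as.integer(sub("codon_pos_", "", class))
    genes <- f$name[f$category == "PCG"]
    if (!length(genes)) abort("record has no PCG features")
    info <- code_info(code_id)
    bases <- unlist(lapply(genes, function(g) {
      codons <- seq_codons(feature_sequence(x, g))
      codons <- codons[!codons %in% info$stops]
      substr(codons, pos, pos)
    }))
    return(paste(bases, collapse = ""))
  }
  abort(sprintf("unknown composition class '%s'", class))
}

#' Composition profiles per gene class
#'
#' Concatenates each class's subsequences and profiles the result. Strand
#' conventions: every feature is extracted on its own sense strand, so
#' PCG and codon-position classes are coding-strand, and rRNA composition
#' is reported on the rRNAs' sense (N) strand — the convention that gives
#' the strongly T-biased rRNA figures mitogenome papers print. The
#' `genome` class is the J-strand as stored. Codon positions use complete
#' codons only, terminal stop codons excluded.
#'
#' @param x a `mitogenome` record with sequence.
#' @param classes character vector over `genome`, `PCG`, `tRNA`, `rRNA`,
#'   `control`, `codon_pos_1`, `codon_pos_2`, `codon_pos_3`.
#' @param code_id genetic code id used to spot stop codons (default 5).
#' @return tibble with one row per class (`class` column plus the
#'   [composition_profile()] columns).
#' @export
class_composition <- function(x, classes = c("genome", "PCG", "tRNA",
                                             "rRNA", "control"),
                              code_id = 5) {
  purrr::map_dfr(classes, function(cl) {
    mutate(composition_profile(class_sequence(x, cl, code_id)),
           class = cl, .before = 1)
  })
}
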