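# Codon usage and RSCU. RSCU (relative synonymous codon usage) scales each
# codon's count so that uniform use within its synonymous family gives 1:
# RSCU_c = n_c * d_aa / sum(n_c' over the family), d_aa = family size.

# DNA codon -> RNA display token (mitogenome figures print UUA etc.)
rna_codon <- function(codon) chartr("T", "U", codon)

#' Count codons across a set of coding sequences
#'
#' Counts complete codons only, pooled across the set; stop codons and
#' trailing incomplete codons (the truncated T--/TA- stops) are excluded,
#' as is conventional for mitogenome codon-usage tables. Codons containing
#' N are skipped.
#'
#' @param cds_set character vector (or list) of coding-strand CDS, each in
#'   frame from its first codon; a single string is accepted.
#' @param code_id NCBI genetic code id (default 5, invertebrate mito).
#' @return object of class `codon_usage`: a tibble with columns `codon`
#'   (RNA-style), `aa`, `count`, `frequency_pct`, `rscu`, plus attributes
#'   `code_id` and `total_codons`.
#' @examples
#' count_codons("ATGTTATTATAA") # 3 counted codons, UUA twice
#' @export
count_codons <- function(cds_set, code_id = 5) {
  cds_set <- vapply(as.list(cds_set), norm_seq, character(1))
  if (any(nchar(cds_set) < 3L)) abort("CDS shorter than one codon")
  info <- code_info(code_id)
  codons <- unlist(lapply(cds_set, seq_codons))
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  codons <- codons[!codons %in% info$stops]
  sense <- setdiff(names(info$code), info$stops)
  counts <- table(factor(codons, levels = sense))
  total <- sum(counts)
  tab <- tibble(
    codon = rna_codon(sense),
    aa = unname(info$code[sense]),
    count = as.integer(counts),
    frequency_pct = if (total > 0) 100 * as.integer(counts) / total else NA_real_
  )
  tab <- mutate(tab, rscu = rscu(.data$count, .data$aa))
  structure(tab, class = c("codon_usage", class(tab)),
            code_id = code_id, total_codons = total)
}

#' Relative synonymous codon usage from codon counts
#'
#' `RSCU = count * degeneracy / family total`; a family with zero total
#' occurrences has undefined RSCU (`NA`), while an unused codon inside a
#' used family scores 0. Within every used family the RSCU values sum to
#' the family's degeneracy.
#'
#' @param count integer codon counts.
#' @param aa amino acid (one-letter) of each codon, defining the
#'   synonymous families. Alternatively pass a `codon_usage` object as the
#'   single argument.
#' @return numeric RSCU vector aligned with `count`.
#' @export
rscu <- function(count, aa = NULL) {
  if (inherits(count, "codon_usage")) {
    aa <- count$aa
    count <- count$count
  }
  stopifnot(length(count) == length(aa))
  fam_total <- stats::ave(count, aa, FUN = sum)
  deg <- stats::ave(count, aa, FUN = length)
  if_else(fam_total > 0, count * deg / fam_total, NA_real_)
}

#' Amino-acid usage percentages from a codon-usage table
#'
#' @param table a `codon_usage` object from [count_codons()].
#' @return tibble `aa`, `count`, `pct` (percent of total counted codons,
#'   stops excluded), sorted by decreasing use.
#' @export
amino_acid_usage <- function(table) {
  stopifnot(inherits(table, "codon_usage"))
  if (sum(table$count) == 0L) abort("codon-usage table has zero counts")
  table |>
    as_tibble() |>
    group_by(.data$aa) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    filter(.data$count > 0) |>
    mutate(pct = 100 * .data$count / sum(.data$count)) |>
    arrange(dplyr::desc(.data$count))
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("<codon_usage> %d codons counted under genetic code %s\n",
              attr(x, "total_codons"), attr(x, "code_id")))
  NextMethod()
}

#' @describeIn count_codons tibble view of the table (drops the class).
#' @param x a `codon_usage` object.
#' @param ... unused.
#' @export
tidy.codon_usage <- function(x, ...) as_tibble(x)

#' @describeIn count_codons one-row summary: total codons, modal codon and
#'   its frequency.
#' @export
glance.codon_usage <- function(x, ...) {
  top <- as_tibble(x) |> arrange(dplyr::desc(.data$count))
  tibble(
    total_codons = attr(x, "total_codons"),
    code_id = attr(x, "code_id"),
    modal_codon = top$codon[1],
    modal_codon_pct = top$frequency_pct[1]
  )
}
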