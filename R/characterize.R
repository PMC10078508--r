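# One-call characterization bundle: the announcement-style battery over a single
# record, with sequence-dependent stages skipped (and said so) when only a
# coordinate table is available. Every number in the human-readable TSVs
# is also present in the machine-readable JSON.

#' Characterize an annotated mitogenome
#'
#' Runs the full descriptive battery: recomputed feature table (sizes and
#' intergenic distances from coordinates), layout summary, per-class
#' composition and skews (including codon positions), codon usage + RSCU,
#' control-region repeats, and — when ortholog alignments are supplied —
#' the per-gene Pi / Ka/Ks divergence panel.
#'
#' @param x a `mitogenome` record (see [read_feature_table()],
#'   [read_genbank()], [generate_mitogenome()]).
#' @param alignments optional named list of `ortholog_alignment` objects
#'   (or a directory path for [read_alignment_dir()]).
#' @param code_id NCBI genetic code id (default 5).
#' @param min_repeat_len minimum repeat motif length in bp (default 9).
#' @param round_digits decimals for reported skews/percentages (default 2,
#'   the precision mitogenome papers print; internal values stay full
#'   precision).
#' @return object of class `mito_report`: list of tibbles (`feature_table`,
#'   `layout_summary`, `strand_tallies`, `composition`, `codon_usage`,
#'   `amino_acids`, `pcg_ends`, `repeats`, `divergence`) plus `skipped`,
#'   a character vector naming stages skipped for lack of sequence, and
#'   `config`.
#' @export
characterize <- function(x, alignments = NULL, code_id = 5,
                         min_repeat_len = 9, round_digits = 2) {
  stopifnot(inherits(x, "mitogenome"))
  config <- list(code_id = code_id, min_repeat_len = min_repeat_len,
                 round_digits = round_digits, id = x$id)
  lay <- layout_report(x)
  out <- list(
    feature_table = lay$features,
    layout_summary = lay$summary,
    strand_tallies = lay$strand_tallies,
    skipped = character(0),
    config = config
  )
  rd <- function(df) mutate(df, across(dplyr::where(is.double),
                                       ~ round(.x, round_digits)))

  if (is.null(x$sequence)) {
    out$skipped <- c(composition = "skipped: sequence required",
                     codon_usage = "skipped: sequence required",
                     repeats = "skipped: sequence required",
                     pcg_ends = "skipped: sequence required")
  } else {
    classes <- c("genome", "PCG", "tRNA", "rRNA", "control",
                 "codon_pos_1", "codon_pos_2", "codon_pos_3")
    have <- unique(x$features$category)
    classes <- classes[classes == "genome" |
                         classes %in% have |
                         (startsWith(classes, "codon_pos") & "PCG" %in% have)]
    out$composition <- rd(class_composition(x, classes, code_id))
    pcgs <- x$features$name[x$features$category == "PCG"]
    if (length(pcgs)) {
      cds <- vapply(pcgs, function(g) feature_sequence(x, g), character(1))
      usage <- count_codons(cds, code_id)
      out$codon_usage <- rd(tidy(usage))
      out$codon_usage_total <- attr(usage, "total_codons")
      out$amino_acids <- rd(amino_acid_usage(usage))
      out$pcg_ends <- pcg_end_table(x, code_id)
    }
    ctrl <- x$features$name[x$features$category == "control"]
    if (length(ctrl) == 1L) {
      hits <- find_repeats(feature_sequence(x, ctrl), min_repeat_len)
      out$repeats <- mutate(hits,
                            positions = map_chr(.data$positions,
                                                paste, collapse = ","))
    }
  }

  if (!is.null(alignments)) {
    if (is.character(alignments)) alignments <- read_alignment_dir(alignments)
    out$divergence <- rd(gene_panel(alignments, code_id))
  }
  structure(out, class = "mito_report")
}

#' @export
print.mito_report <- function(x, ...) {
  cat(sprintf("<mito_report> %s\n", x$config$id))
  print(x$layout_summary)
  if (length(x$skipped)) {
    cat("skipped stages:\n")
    for (s in names(x$skipped)) cat(sprintf("  %s: %s\n", s, x$skipped[[s]]))
  }
  invisible(x)
}

#' Write a characterization report bundle to disk
#'
#' One TSV per table plus a single JSON carrying every table and the run
#' config; floats already rounded per the report's config; `NA` values are
#' written as the literal `NA` token in TSVs. Output is deterministic:
#' identical input gives byte-identical files.
#'
#' @param report a `mito_report` from [characterize()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mito_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- keep(report, is.data.frame)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tables[[nm]], p, na = "NA", progress = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(
    c(tables, list(skipped = as.list(report$skipped),
                   config = report$config)),
    jp, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(c(paths, jp))
}
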