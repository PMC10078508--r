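# Tab-separated feature-table dialect mirroring the characteristics table
# of mitogenome papers: columns name, strand (J/N), start, stop and
# optionally start_codon / stop_codon; header row required; N-strand rows
# may be written with start > stop (as printed) and are normalised on read.

#' Path to a bundled example file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return path (or character vector of file names).
#' @export
mitochar_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "mitochar")))
  }
  path <- system.file("extdata", file, package = "mitochar")
  if (path == "") abort(sprintf("no bundled file '%s'", file))
  path
}

#' Read a gene feature table (and optional genome FASTA)
#'
#' @param table_path TSV feature table in the dialect above.
#' @param fasta_path optional genome FASTA; without it the record supports
#'   layout/length analyses only and sequence-dependent operations error.
#' @param id record identifier; defaults to the table file name.
#' @return a `mitogenome` record. Genome length is taken from the FASTA
#'   when present, otherwise inferred as `max(stop)`.
#' @examples
#' read_feature_table(mitochar_example("cryptotermes_domesticus_features.tsv"))
#' @export
read_feature_table <- function(table_path, fasta_path = NULL, id = NULL) {
  tab <- readr::read_tsv(table_path, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(tab) == 0L) abort("empty feature table")
  required <- c("name", "strand", "start", "stop")
  if (!all(required %in% names(tab))) {
    abort(sprintf("feature table must have columns: %s",
                  paste(required, collapse = ", ")))
  }
  if (!is.numeric(tab$start) || !is.numeric(tab$stop)) {
    abort("non-integer coordinates in feature table")
  }
  if (!all(tab$strand %in% c("J", "N"))) {
    abort("strand token outside {J, N}")
  }
  # N-strand rows printed 5'->3' on their own strand have start > stop;
  # normalise to start < stop in J-strand coordinates (wrap-around features
  # are only expected from GenBank join() input, not this dialect).
  lo <- pmin(tab$start, tab$stop)
  hi <- pmax(tab$start, tab$stop)
  feats <- gene_features(tab$name, tab$strand, lo, hi)
  sequence <- NULL
  if (!is.null(fasta_path)) {
    dna <- Biostrings::readDNAStringSet(fasta_path)
    if (length(dna) != 1L) abort("genome FASTA must contain one sequence")
    sequence <- norm_seq(dna[[1]])
  }
  mitogenome_record(feats, sequence = sequence,
                    id = id %||% basename(table_path))
}

#' Write a record's features in the TSV feature-table dialect
#'
#' Coordinates are written normalised (start <= stop except wrap-around
#' features); read -> write -> read round-trips to the identical record.
#'
#' @param x a `mitogenome` record.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "mitogenome"))
  readr::write_tsv(select(x$features, "name", "strand", "start", "stop"),
                   path, progress = FALSE)
  invisible(path)
}

#' Write the genome sequence of a record as FASTA
#'
#' @param x a `mitogenome` record with sequence.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(x, path) {
  if (is.null(x$sequence)) abort("sequence required")
  dna <- Biostrings::DNAStringSet(setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}
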