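# The mitogenome record: circular J-strand sequence (optional) + ordered
# feature tibble + metadata. A light S3 list, not S4: the feature tibble is
# the object users actually manipulate.

#' Assemble a mitogenome record
#'
#' @param features feature tibble from [gene_features()] (or a data frame
#'   with the same columns, which will be validated).
#' @param length genome length in bp; inferred from `max(stop)` when a
#'   sequence is absent and `length` is missing.
#' @param sequence optional J-strand nucleotide string over `{A,C,G,T,N}`.
#' @param id free-text identifier.
#' @param circular logical; insect mitogenomes are circular.
#' @return object of class `mitogenome`.
#' @export
mitogenome_record <- function(features, length = NULL, sequence = NULL,
                              id = "mitogenome", circular = TRUE) {
  if (!is_tibble(features)) features <- as_tibble(features)
  features <- gene_features(features$name, features$strand,
                            features$start, features$stop,
                            category = features[["category"]])
  if (!is.null(sequence)) {
    sequence <- norm_seq(sequence)
    if (!is.null(length) && nchar(sequence) != length) {
      abort("sequence length does not match declared genome length")
    }
    length <- nchar(sequence)
  }
  length <- length %||% max(features$stop)
  if (any(features$start > length | features$stop > length)) {
    abort("feature coordinates outside [1, genome length]")
  }
  if (anyDuplicated(features$name)) {
    abort(sprintf("duplicate gene names: %s",
                  paste(unique(features$name[duplicated(features$name)]),
                        collapse = ", ")))
  }
  structure(
    list(id = id, length = as.integer(length), circular = circular,
         sequence = sequence, features = features),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: %s bp (%s), %d features%s%s\n",
              x$id, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features),
              if (is.null(x$sequence)) ", no sequence" else "",
              if (is_complete(x)) ", complete gene set" else ""))
  print(x$features, n = 5)
  invisible(x)
}

#' Does a record carry the canonical 37-gene mitogenome set?
#'
#' Canonical = 13 PCGs + 22 tRNAs + 2 rRNAs plus one control region.
#'
#' @param x a `mitogenome` record.
#' @return logical scalar.
#' @export
is_complete <- function(x) {
  stopifnot(inherits(x, "mitogenome"))
  f <- x$features
  setequal(f$name[f$category == "PCG"], canonical_pcg_order) &&
    setequal(f$name[f$category == "tRNA"], canonical_trna) &&
    setequal(f$name[f$category == "rRNA"], c("rrnL", "rrnS")) &&
    sum(f$category == "control") == 1L
}

#' Extract a feature's sequence in sense orientation
#'
#' Substrings the J-strand sequence (wrapping the origin when `start >
#' stop`) and reverse-complements N-strand features, so the result reads
#' 5'->3' on the feature's own coding/sense strand.
#'
#' @param x a `mitogenome` record with sequence.
#' @param name gene token of the feature to extract.
#' @return character scalar.
#' @export
feature_sequence <- function(x, name) {
  stopifnot(inherits(x, "mitogenome"))
  if (is.null(x$sequence)) {
    abort("sequence required: this record carries coordinates only")
  }
  i <- match(name, x$features$name)
  if (is.na(i)) abort(sprintf("no feature named '%s'", name))
  f <- x$features[i, ]
  s <- if (f$stop >= f$start) {
    substr(x$sequence, f$start, f$stop)
  } else {
    paste0(substr(x$sequence, f$start, x$length), substr(x$sequence, 1L, f$stop))
  }
  if (f$strand == "N") revcomp(s) else s
}

#' Start/stop codon classification for every PCG of a record
#'
#' @param x a `mitogenome` record with sequence.
#' @param code_id NCBI genetic code id (default 5).
#' @return tibble: name, start_codon, stop_codon, complete.
#' @export
pcg_end_table <- function(x, code_id = 5) {
  pcgs <- filter(x$features, .data$category == "PCG")$name
  purrr::map_dfr(pcgs, function(g) {
    mutate(classify_ends(feature_sequence(x, g), code_id), name = g,
           .before = 1)
  })
}
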