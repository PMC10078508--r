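# Gene features on a circular genome. Coordinates are 1-based inclusive on
# the J-strand (the table convention of mitogenome papers); N-strand
# features are stored with start < stop and reverse-complemented on
# extraction. A feature wrapping the circular origin has start > stop.

canonical_pcg_order <- c(
  "atp6", "atp8", "cox1", "cox2", "cox3", "cytb",
  "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6"
)

canonical_trna <- paste0("trn", c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2", "M", "N",
  "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y"
))

#' Infer the feature category from a canonical gene token
#'
#' `trn*` is tRNA, `rrn*` is rRNA, `d-loop` is the control region, anything
#' else is treated as protein-coding.
#'
#' @param name character vector of gene tokens.
#' @return character vector over `{PCG, tRNA, rRNA, control}`.
#' @export
feature_category <- function(name) {
  dplyr::case_when(
    startsWith(name, "trn") ~ "tRNA",
    startsWith(name, "rrn") ~ "rRNA",
    name %in% c("d-loop", "dloop", "control", "AT-rich") ~ "control",
    TRUE ~ "PCG"
  )
}

#' Build and validate a gene-feature tibble
#'
#' The central tabular container of the package: one row per annotated gene
#' with canonical token, strand (J = majority, N = minority), and 1-based
#' inclusive J-strand coordinates. Rows are sorted by start position.
#'
#' @param name gene tokens (e.g. `cox1`, `trnS2`, `rrnL`, `d-loop`).
#' @param strand `"J"` or `"N"` per feature.
#' @param start,stop 1-based inclusive positions; `start > stop` marks a
#'   feature wrapping the circular origin.
#' @param category optional; inferred from `name` when missing.
#' @param genome_length optional; when given, coordinates are range-checked.
#' @return tibble with columns name, category, strand, start, stop.
#' @examples
#' gene_features(c("cox1", "trnY"), c("J", "N"), c(1437, 1368), c(2981, 1435))
#' @export
gene_features <- function(name, strand, start, stop, category = NULL,
                          genome_length = NULL) {
  start <- as.integer(start)
  stop <- as.integer(stop)
  if (!all(strand %in% c("J", "N"))) {
    abort("strand tokens must be 'J' or 'N'")
  }
  if (anyNA(start) || anyNA(stop) || any(start < 1L) || any(stop < 1L)) {
    abort("start/stop must be positive integers")
  }
  if (!is.null(genome_length) &&
      (any(start > genome_length) || any(stop > genome_length))) {
    abort("feature coordinates outside [1, genome length]")
  }
  category <- category %||% feature_category(name)
  ok <- (category == "tRNA") == startsWith(name, "trn") &
    (category == "rRNA") == startsWith(name, "rrn")
  if (!all(ok)) {
    abort("category inconsistent with gene-name prefix")
  }
  tibble(name = name, category = category, strand = strand,
         start = start, stop = stop) |>
    arrange(.data$start, .data$stop)
}

#' Feature length on a circular genome
#'
#' Vectorised over features; a feature with `stop < start` wraps the origin
#' and contributes `(genome_length - start + 1) + stop` bases.
#'
#' @param start,stop 1-based inclusive coordinates.
#' @param genome_length total genome length in bp.
#' @return integer vector of lengths (always >= 1).
#' @examples
#' feature_length(1437, 2981, 15655) # cox1-sized: 1545
#' @export
feature_length <- function(start, stop, genome_length) {
  start <- as.integer(start)
  stop <- as.integer(stop)
  if (any(start < 1L | stop < 1L | start > genome_length | stop > genome_length)) {
    abort("coordinates outside [1, genome length]")
  }
  as.integer(ifelse(stop >= start, stop - start + 1L,
                    (genome_length - start + 1L) + stop))
}

#' Signed intergenic distance between two adjacent features
#'
#' Positive values are spacers, negative values overlaps, zero means the
#' genes abut. Both strands share the J-strand coordinate system.
#'
#' @param prev_stop stop of the upstream feature (J-strand order).
#' @param next_start start of the downstream feature.
#' @param genome_length genome length; needed only for the wrap-around pair.
#' @param wrap evaluate the pair across the circular origin.
#' @return integer signed bp.
#' @examples
#' intergenic(11573, 11597) # the trnS2 -> nad1 spacer: 23
#' intergenic(9461, 9455)   # the nad4/nad4l overlap: -7
#' @export
intergenic <- function(prev_stop, next_start, genome_length = NULL,
                       wrap = FALSE) {
  if (wrap) {
    stopifnot(!is.null(genome_length))
    as.integer((genome_length - prev_stop) + next_start - 1L)
  } else {
    as.integer(next_start - prev_stop - 1L)
  }
}

#' Circular layout report: sizes, spacers, overlaps, strand tallies
#'
#' Recomputes every per-feature size and every adjacent-pair intergenic
#' distance from coordinates (never trusting a printed column), including
#' the wrap-around pair for circular records. Overlaps involving an rRNA
#' are tallied separately because rRNA boundaries are annotation-soft.
#'
#' @param x a `mitogenome` record (see [mitogenome_record()]) or a feature
#'   tibble from [gene_features()].
#' @param genome_length required when `x` is a bare feature tibble.
#' @param circular evaluate the last->first pair across the origin.
#' @return object of class `mito_layout`: list with `features` (tibble with
#'   size and gap-to-next columns), `pairs`, `summary` (one-row tibble) and
#'   `strand_tallies`.
#' @examples
#' tbl <- read_feature_table(mitochar_example("cryptotermes_domesticus_features.tsv"))
#' layout_report(tbl)$summary
#' @export
layout_report <- function(x, genome_length = NULL, circular = TRUE) {
  if (inherits(x, "mitogenome")) {
    feats <- x$features
    genome_length <- x$length
    circular <- x$circular
  } else {
    feats <- x
    genome_length <- genome_length %||% max(feats$stop)
  }
  if (is.unsorted(feats$start)) {
    abort("features must be sorted by start position")
  }
  if (any(feats$start > genome_length | feats$stop > genome_length)) {
    abort("feature coordinates outside [1, genome length]")
  }
  feats <- feats |>
    mutate(size = feature_length(.data$start, .data$stop, genome_length))

  n <- nrow(feats)
  gap_next <- c(
    intergenic(feats$stop[-n], feats$start[-1]),
    if (circular) intergenic(feats$stop[n], feats$start[1],
                             genome_length, wrap = TRUE) else NA_integer_
  )
  feats$gap_next <- gap_next

  pairs <- tibble(
    upstream = feats$name,
    downstream = c(feats$name[-1], feats$name[1]),
    gap = gap_next,
    rrna_involved = startsWith(feats$name, "rrn") |
      startsWith(c(feats$name[-1], feats$name[1]), "rrn")
  ) |>
    filter(!is.na(.data$gap))

  spacers <- filter(pairs, .data$gap > 0)
  overlaps <- filter(pairs, .data$gap < 0, !.data$rrna_involved)
  overlaps_rrna <- filter(pairs, .data$gap < 0, .data$rrna_involved)

  pick_extreme <- function(df) {
    if (nrow(df) == 0L) return(list(bp = NA_integer_, pair = NA_character_))
    i <- order(abs(df$gap), decreasing = TRUE)[1]
    list(bp = abs(df$gap[i]),
         pair = paste(df$upstream[i], df$downstream[i], sep = "-"))
  }
  sp <- pick_extreme(spacers)
  ov <- pick_extreme(overlaps)

  tallies <- feats |>
    filter(.data$category != "control") |>
    dplyr::count(.data$strand, .data$category, name = "n_genes")

  summary <- tibble(
    genome_length = as.integer(genome_length),
    n_features = n,
    n_spacers = nrow(spacers),
    n_overlaps = nrow(overlaps),
    n_overlaps_rrna = nrow(overlaps_rrna),
    longest_spacer_bp = sp$bp, longest_spacer_pair = sp$pair,
    longest_overlap_bp = ov$bp, longest_overlap_pair = ov$pair,
    j_strand_genes = sum(feats$strand == "J" & feats$category != "control"),
    n_strand_genes = sum(feats$strand == "N" & feats$category != "control"),
    total_feature_bp = sum(feats$size),
    conservation_ok = isTRUE(
      circular && sum(feats$size) + sum(pairs$gap) == genome_length
    )
  )

  structure(
    list(features = feats, pairs = pairs, summary = summary,
         strand_tallies = tallies, circular = circular),
    class = "mito_layout"
  )
}

#' @export
print.mito_layout <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<mito_layout> %d features on %s bp (%s)\n",
    s$n_features, format(s$genome_length, big.mark = ","),
    if (x$circular) "circular" else "linear"
  ))
  cat(sprintf("  spacers: %d (longest %s bp, %s)\n",
              s$n_spacers, s$longest_spacer_bp, s$longest_spacer_pair))
  cat(sprintf("  overlaps: %d non-rRNA (longest %s bp, %s) + %d rRNA-involved\n",
              s$n_overlaps, s$longest_overlap_bp, s$longest_overlap_pair,
              s$n_overlaps_rrna))
  cat(sprintf("  strand J: %d genes / strand N: %d genes\n",
              s$j_strand_genes, s$n_strand_genes))
  invisible(x)
}

#' @describeIn layout_report per-feature tibble with recomputed sizes and
#'   gaps to the next feature.
#' @param ... unused.
#' @export
tidy.mito_layout <- function(x, ...) x$features

#' @describeIn layout_report one-row summary tibble.
#' @export
glance.mito_layout <- function(x, ...) x$summary

#' Classify the start and stop codons of a coding sequence
#'
#' Mitochondrial PCGs commonly end on truncated stop codons (`T--` or
#' `TA-`) that are completed to TAA by polyadenylation of the transcript.
#' The final triplet of an in-frame CDS is its stop; a CDS whose length
#' leaves a remainder of 1 (ending in T) or 2 (ending in TA) carries an
#' incomplete stop and is flagged `complete = FALSE`.
#'
#' @param cds coding-strand sequence, 5'->3', length >= 4.
#' @param code_id NCBI genetic code id (default 5).
#' @return one-row tibble: `start_codon`, `stop_codon` (one of TAA/TAG/
#'   `T--`/`TA-`), `complete`.
#' @examples
#' classify_ends("ATGAAATAA") # complete TAA stop
#' @export
classify_ends <- function(cds, code_id = 5) {
  cds <- norm_seq(cds)
  if (nchar(cds) < 4L) abort("CDS shorter than 4 bases")
  info <- code_info(code_id)
  start_codon <- substr(cds, 1L, 3L)
  rem <- nchar(cds) %% 3L
  if (rem == 0L) {
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (!last %in% info$stops) {
      abort(sprintf("malformed CDS: final codon %s is not a stop codon", last))
    }
    stop_codon <- last
    complete <- TRUE
  } else if (rem == 1L) {
    if (substr(cds, nchar(cds), nchar(cds)) != "T") {
      abort("malformed CDS: length remainder 1 but trailing base is not T")
    }
    stop_codon <- "T--"
    complete <- FALSE
  } else {
    if (substr(cds, nchar(cds) - 1L, nchar(cds)) != "TA") {
      abort("malformed CDS: length remainder 2 but trailing bases are not TA")
    }
    stop_codon <- "TA-"
    complete <- FALSE
  }
  tibble(start_codon = start_codon, stop_codon = stop_codon,
         complete = complete)
}
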