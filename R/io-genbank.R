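# Minimal GenBank flat-file reader/writer for annotated mitogenomes.
# Handles LOCUS, the FEATURES table (CDS / tRNA / rRNA / D-loop /
# misc_feature keys with a..b, complement(a..b) and origin-wrapping
# join(a..b,c..d) locations) and the ORIGIN sequence block — the subset of
# the format that mitogenome records actually use.

# synonym map: upper-cased GenBank gene/product tokens -> canonical tokens
.gene_synonyms <- local({
  syn <- c(
    COX1 = "cox1", COI = "cox1", CO1 = "cox1",
    COX2 = "cox2", COII = "cox2", CO2 = "cox2",
    COX3 = "cox3", COIII = "cox3", CO3 = "cox3",
    CYTB = "cytb", COB = "cytb", CYB = "cytb",
    ATP6 = "atp6", ATPASE6 = "atp6", ATP8 = "atp8", ATPASE8 = "atp8",
    ND1 = "nad1", ND2 = "nad2", ND3 = "nad3", ND4 = "nad4",
    ND4L = "nad4l", ND5 = "nad5", ND6 = "nad6",
    `16S` = "rrnL", LRRNA = "rrnL", `L-RRNA` = "rrnL", RRNL = "rrnL",
    `12S` = "rrnS", SRRNA = "rrnS", `S-RRNA` = "rrnS", RRNS = "rrnS",
    `D-LOOP` = "d-loop", DLOOP = "d-loop", `AT-RICH` = "d-loop",
    `CONTROL REGION` = "d-loop"
  )
  for (g in c(canonical_pcg_order, canonical_trna, "rrnL", "rrnS")) {
    syn[[toupper(g)]] <- g
  }
  syn
})

canonical_gene_name <- function(token) {
  hit <- .gene_synonyms[toupper(trimws(token))]
  if (is.na(hit)) token else unname(hit)
}

parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "J"
  if (startsWith(loc, "complement(")) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (startsWith(loc, "join(")) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
    rng <- do.call(rbind, lapply(parts, function(p) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    }))
    if (nrow(rng) != 2L) abort(sprintf("unsupported join() location: %s", loc))
    # origin-wrapping feature: first segment runs to the genome end
    return(list(start = rng[1, 1], stop = rng[2, 2], strand = strand))
  }
  ends <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  if (length(ends) == 1L) ends <- c(ends, ends)
  if (length(ends) != 2L || anyNA(ends)) {
    abort(sprintf("unparseable GenBank location: %s", loc))
  }
  list(start = ends[1], stop = ends[2], strand = strand)
}

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Gene names are mapped to canonical tokens through a synonym table
#' (COI -> cox1, ND4L -> nad4l, 16S -> rrnL, ...); unknown names are kept
#' with a warning and categorised from the feature key, never dropped.
#' `complement(...)` locations become strand N; an origin-wrapping
#' `join(a..L, 1..b)` becomes a single wrapping feature.
#'
#' @param path GenBank flat file.
#' @return a `mitogenome` record with sequence (when an ORIGIN block is
#'   present) and features.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2] else basename(path)

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  end <- grep("^//", lines)
  if (!length(feat_start)) abort("no FEATURES block found")

  feat_end <- if (length(origin_start)) origin_start[1] - 1L else
    if (length(end)) end[1] - 1L else length(lines)
  flines <- lines[(feat_start[1] + 1L):feat_end]

  keys_of_interest <- c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")
  is_key <- grepl("^ {1,10}\\S", flines) & !grepl("^ {12,}", flines)
  key_idx <- which(is_key)
  feats <- list()
  for (k in seq_along(key_idx)) {
    i <- key_idx[k]
    j <- if (k < length(key_idx)) key_idx[k + 1] - 1L else length(flines)
    header <- strsplit(trimws(flines[i]), "\\s+")[[1]]
    key <- header[1]
    if (!key %in% keys_of_interest) next
    block <- flines[i:j]
    # location may continue over lines until the first qualifier
    qual_at <- grep("^\\s+/", block)
    loc_lines <- block[seq_len(if (length(qual_at)) qual_at[1] - 1L else length(block))]
    loc <- gsub("\\s", "", paste(c(header[-1], trimws(loc_lines[-1])), collapse = ""))
    pos <- parse_gb_location(loc)
    quals <- block[grepl("^\\s+/", block)]
    get_qual <- function(q) {
      hit <- grep(sprintf("^\\s+/%s=", q), quals, value = TRUE)
      if (!length(hit)) return(NULL)
      gsub('^[^=]+="?|"$', "", hit[1])
    }
    raw_name <- get_qual("gene") %||% get_qual("product") %||% key
    name <- canonical_gene_name(raw_name)
    known <- name %in% c(canonical_pcg_order, canonical_trna, "rrnL", "rrnS",
                         "d-loop")
    if (!known) {
      warn(sprintf("unknown gene name '%s' kept as-is (feature key %s)",
                   raw_name, key))
    }
    category <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                       "control")
    if (known) category <- feature_category(name)
    feats[[length(feats) + 1L]] <- tibble(
      name = name, category = category, strand = pos$strand,
      start = pos$start, stop = pos$stop
    )
  }
  if (!length(feats)) abort("no gene features found in GenBank file")
  feats <- bind_rows(feats)
  if (anyDuplicated(feats$name)) {
    abort(sprintf("duplicate canonical gene names in GenBank file: %s",
                  paste(unique(feats$name[duplicated(feats$name)]),
                        collapse = ", ")))
  }

  sequence <- NULL
  if (length(origin_start)) {
    seq_lines <- lines[(origin_start[1] + 1L):(end[1] - 1L)]
    sequence <- norm_seq(gsub("[ 0-9/]", "", paste(seq_lines, collapse = "")))
  }
  feats <- feats |> arrange(.data$start, .data$stop)
  mitogenome_record(
    gene_features(feats$name, feats$strand, feats$start, feats$stop,
                  category = feats$category),
    sequence = sequence, id = id
  )
}

#' Write a mitogenome record as a GenBank flat file
#'
#' Emits LOCUS, a FEATURES table (CDS/tRNA/rRNA/D-loop keys, `/gene`
#' qualifiers with canonical tokens, `complement(...)` for N-strand
#' features) and the ORIGIN block; [read_genbank()] round-trips it.
#'
#' @param x a `mitogenome` record with sequence.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(x, path) {
  stopifnot(inherits(x, "mitogenome"))
  if (is.null(x$sequence)) abort("sequence required to write GenBank")
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("LOCUS       %s %d bp    DNA     %s   INV", x$id, x$length,
     if (x$circular) "circular" else "linear")
  wl("DEFINITION  %s, synthetic or reannotated mitogenome record.", x$id)
  wl("FEATURES             Location/Qualifiers")
  wl("     source          1..%d", x$length)
  wl("                     /organelle=\"mitochondrion\"")
  for (i in seq_len(nrow(x$features))) {
    f <- x$features[i, ]
    key <- switch(f$category, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  "D-loop")
    loc <- if (f$stop >= f$start) {
      sprintf("%d..%d", f$start, f$stop)
    } else {
      sprintf("join(%d..%d,1..%d)", f$start, x$length, f$stop)
    }
    if (f$strand == "N") loc <- sprintf("complement(%s)", loc)
    wl("     %-15s %s", key, loc)
    wl("                     /gene=\"%s\"", f$name)
  }
  wl("ORIGIN")
  pos <- seq(1L, x$length, by = 60L)
  for (p in pos) {
    chunk <- substr(x$sequence, p, min(p + 59L, x$length))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    wl("%9d %s", p, tolower(paste(tens, collapse = " ")))
  }
  wl("//")
  invisible(path)
}
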