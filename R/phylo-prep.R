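# Concatenated 13-PCG supermatrix preparation: terminal-stop trimming,
# codon-column gap/ambiguity filtering (a strict, Gblocks-like default),
# concatenation under the canonical PCG order with partition bookkeeping,
# and a neighbor-joining sanity tree over p- or JC-corrected distances.

#' Strip the terminal stop codon column-triplet from a codon alignment
#'
#' Removed only when every non-gap sequence ends in a stop codon; an
#' internal stop anywhere raises a frame error naming taxon and codon.
#'
#' @param aln an `ortholog_alignment`.
#' @param code_id NCBI genetic code id (default 5).
#' @return the alignment, 3 columns shorter when a stop triplet was
#'   trimmed, otherwise unchanged.
#' @export
strip_stops <- function(aln, code_id = 5) {
  if (!inherits(aln, "ortholog_alignment")) aln <- ortholog_alignment(aln)
  info <- code_info(code_id)
  seqs <- unclass(aln)
  n_cod <- nchar(seqs[1]) %/% 3L
  for (tx in names(seqs)) {
    codons <- seq_codons(seqs[[tx]])
    internal <- which(codons[-n_cod] %in% info$stops)
    if (length(internal)) {
      abort(sprintf("internal stop codon in taxon '%s' at codon %d",
                    tx, internal[1]))
    }
  }
  last <- vapply(seqs, function(s) substr(s, nchar(s) - 2L, nchar(s)),
                 character(1))
  nongap <- last != "---"
  if (any(nongap) && all(last[nongap] %in% info$stops)) {
    seqs <- vapply(seqs, function(s) substr(s, 1L, nchar(s) - 3L),
                   character(1))
  }
  ortholog_alignment(seqs, attr(aln, "gene"))
}

#' Filter gappy/ambiguous codon columns from an alignment
#'
#' Codon-column triplets in which the fraction of sequences containing a
#' gap or ambiguity (anything outside A/C/G/T) exceeds `max_gap_fraction`
#' are removed whole, preserving the reading frame. The strict default
#' (0) drops a codon column as soon as a single sequence is gapped or
#' ambiguous there — a deliberately conservative stand-in for Gblocks-style
#' ambiguous-site removal.
#'
#' @param aln an `ortholog_alignment`.
#' @param max_gap_fraction tolerated fraction in `[0, 1]`; default 0.
#' @return the filtered alignment.
#' @export
filter_columns <- function(aln, max_gap_fraction = 0) {
  if (!inherits(aln, "ortholog_alignment")) aln <- ortholog_alignment(aln)
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  seqs <- unclass(aln)
  cod <- lapply(seqs, seq_codons)
  n_cod <- length(cod[[1]])
  if (n_cod == 0L) return(aln)
  bad <- vapply(seq_len(n_cod), function(i) {
    frac <- mean(vapply(cod, function(cs) grepl("[^ACGT]", cs[i]), logical(1)))
    frac > max_gap_fraction
  }, logical(1))
  out <- vapply(cod, function(cs) paste(cs[!bad], collapse = ""), character(1))
  ortholog_alignment(setNames(out, names(seqs)), attr(aln, "gene"))
}

#' Concatenate per-gene alignments into a partitioned supermatrix
#'
#' Genes are laid out in the canonical mitochondrial PCG order (atp6,
#' atp8, cox1..cox3, cytb, nad1..nad6 with nad4l after nad4) regardless of
#' input list order; genes outside that set follow alphabetically. A taxon
#' missing from a gene gets an all-gap block, so all rows stay equal
#' length. Partitions tile the matrix without gaps or overlaps.
#'
#' @param alignments named list of `ortholog_alignment` objects (names =
#'   gene tokens, else each `gene` attribute is used).
#' @param taxa optional character vector fixing the row set and order;
#'   default: union of all taxa, alphabetical.
#' @return object of class `supermatrix`: list with `taxa`, `aln` (named
#'   character vector), `partitions` (tibble gene/start/end, 1-based
#'   inclusive columns) and `length`.
#' @export
concatenate_genes <- function(alignments, taxa = NULL) {
  if (!length(alignments)) abort("no alignments to concatenate")
  if (is.null(names(alignments)) || any(names(alignments) == "")) {
    names(alignments) <- vapply(alignments, function(a) attr(a, "gene"),
                                character(1))
  }
  genes <- names(alignments)
  ord <- c(intersect(canonical_pcg_order, genes),
           sort(setdiff(genes, canonical_pcg_order)))
  alignments <- alignments[ord]
  all_taxa <- taxa %||% sort(unique(unlist(lapply(alignments, names))))
  if (anyDuplicated(all_taxa)) abort("duplicate taxon labels")

  blocks <- imap(alignments, function(aln, gene) {
    L <- nchar(aln[[1]])
    vapply(all_taxa, function(tx) {
      if (tx %in% names(aln)) unclass(aln)[[tx]] else strrep("-", L)
    }, character(1))
  })
  lens <- vapply(blocks, function(b) nchar(b[[1]]), integer(1))
  ends <- cumsum(lens)
  partitions <- tibble(gene = ord,
                       start = as.integer(ends - lens + 1L),
                       end = as.integer(ends))
  aln <- vapply(all_taxa, function(tx) {
    paste(vapply(blocks, function(b) b[[tx]], character(1)), collapse = "")
  }, character(1))
  structure(list(taxa = all_taxa, aln = aln, partitions = partitions,
                 length = sum(lens)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d partitions\n",
              length(x$taxa), x$length, nrow(x$partitions)))
  print(x$partitions, n = 5)
  invisible(x)
}

#' Neighbor-joining sanity tree from a supermatrix or distance matrix
#'
#' A quick topology check for the concatenated matrix before handing the
#' partitioned supermatrix to a real inference program. Taxa are ordered
#' alphabetically first so ties break deterministically; negative NJ
#' branch lengths are clamped to 0.
#'
#' @param x a `supermatrix`, or a symmetric distance matrix with taxon
#'   dimnames (additive distances reproduce their generating topology).
#' @param model `"p-distance"` or `"JC"`; pairwise deletion of gap/N
#'   sites. Ignored when `x` is already a distance matrix.
#' @return an `ape::phylo` tree (write with [write_newick()]).
#' @export
distance_tree <- function(x, model = c("p-distance", "JC")) {
  model <- match.arg(model)
  if (inherits(x, "supermatrix")) {
    if (length(x$taxa) < 3L) abort("need at least 3 taxa for a tree")
    ord <- order(x$taxa)
    chars <- do.call(rbind, strsplit(tolower(x$aln[ord]), "", fixed = TRUE))
    rownames(chars) <- x$taxa[ord]
    bin <- ape::as.DNAbin(chars)
    d <- ape::dist.dna(bin, model = if (model == "JC") "JC69" else "raw",
                       pairwise.deletion = TRUE)
  } else {
    d <- as.matrix(x)
    if (is.null(rownames(d)) || nrow(d) < 3L) {
      abort("distance matrix needs taxon dimnames and >= 3 taxa")
    }
    ord <- order(rownames(d))
    d <- stats::as.dist(d[ord, ord])
  }
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Write a tree in Newick format
#'
#' @param tree an `ape::phylo` object.
#' @param path output file; with `NULL`, the Newick string is returned.
#' @return the path (invisibly) or the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a supermatrix and its partition schemes
#'
#' Emits a relaxed PHYLIP matrix, a FASTA matrix, a RAxML-style partition
#' file (`DNA, gene = start-end`) and a NEXUS sets block with `charset`
#' lines, so downstream ML/BI programs can consume the bundle directly.
#'
#' @param sm a `supermatrix`.
#' @param dir output directory (created if needed).
#' @param stem file name stem (default `"supermatrix"`).
#' @return named character vector of the four written paths, invisibly.
#' @export
write_supermatrix <- function(sm, dir, stem = "supermatrix") {
  stopifnot(inherits(sm, "supermatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    phylip = file.path(dir, paste0(stem, ".phy")),
    fasta = file.path(dir, paste0(stem, ".fasta")),
    raxml = file.path(dir, paste0(stem, ".partitions.txt")),
    nexus = file.path(dir, paste0(stem, ".sets.nex"))
  )
  writeLines(c(sprintf("%d %d", length(sm$taxa), sm$length),
               sprintf("%s  %s", sm$taxa, sm$aln)), paths[["phylip"]])
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(sm$aln, sm$taxa)), paths[["fasta"]])
  writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end),
             paths[["raxml"]])
  writeLines(c("#NEXUS", "begin sets;",
               sprintf("  charset %s = %d-%d;", sm$partitions$gene,
                       sm$partitions$start, sm$partitions$end),
               "end;"), paths[["nexus"]])
  invisible(paths)
}
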