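# Synthetic mitogenome generator. The default template reproduces the
# 38-feature architecture (37 genes + control region) of a drywood-termite
# mitogenome: gene order, strands, coordinates, start/stop codons, the
# 15,655 bp length, the A-rich whole-genome base composition, and a
# control region carrying one 89 bp duplicated motif plus one 9 bp tandem
# repeat. Sequence is sampled per region from the target composition; PCGs
# are built codon-wise so starts, (possibly incomplete) stops and the
# absence of internal stop codons all hold by construction, even across
# gene overlaps.

.comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# proposal fractions whose stop-rejected marginal equals the target
adjust_for_stop_rejection <- function(target, stops) {
  bases <- names(target)
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                      stringsAsFactors = FALSE)
  is_stop <- paste0(grid$b1, grid$b2, grid$b3) %in% stops
  f <- target
  for (k in 1:25) {
    w <- f[grid$b1] * f[grid$b2] * f[grid$b3]
    w[is_stop] <- 0
    w <- w / sum(w)
    marg <- (tapply(w, grid$b1, sum) + tapply(w, grid$b2, sum) +
               tapply(w, grid$b3, sum))[bases] / 3
    f <- f * target / marg
    f <- f / sum(f)
  }
  f
}

#' Default or custom genome template
#'
#' @param features feature tibble with columns name, strand, start, stop
#'   and (for PCGs) start_codon/stop_codon; default: the bundled termite
#'   architecture.
#' @param genome_length total length in bp.
#' @param base_fractions named numeric (A/T/G/C) target composition of
#'   sampled sequence; default `c(A=.418, T=.249, G=.123, C=.210)`.
#' @param repeats control-region repeat spec: list of lists with `len`,
#'   `starts` (region-relative copy starts) — adjacent starts spaced by
#'   `len` give a tandem repeat. Default: 89 bp at 8 and 179 (copies
#'   spanning region positions 8-267) plus a 9 bp tandem pair at 401.
#' @return list of class `genome_template`.
#' @export
genome_template <- function(features = NULL, genome_length = NULL,
                            base_fractions = c(A = 0.418, T = 0.249,
                                               G = 0.123, C = 0.210),
                            repeats = list(
                              list(len = 89L, starts = c(8L, 179L)),
                              list(len = 9L, starts = c(401L, 410L))
                            )) {
  if (is.null(features)) {
    tab <- readr::read_tsv(
      mitochar_example("cryptotermes_domesticus_features.tsv"),
      show_col_types = FALSE, progress = FALSE)
    features <- tibble(
      name = tab$name, strand = tab$strand,
      start = pmin(tab$start, tab$stop), stop = pmax(tab$start, tab$stop),
      start_codon = tab$start_codon, stop_codon = tab$stop_codon
    )
    genome_length <- genome_length %||% max(features$stop)
  }
  genome_length <- genome_length %||% max(features$stop)
  if (any(features$stop > genome_length)) {
    abort("template feature lengths exceed genome length")
  }
  stopifnot(abs(sum(base_fractions) - 1) < 1e-6)
  structure(list(features = features, genome_length = genome_length,
                 base_fractions = base_fractions, repeats = repeats),
            class = "genome_template")
}

#' Generate a synthetic annotated mitogenome
#'
#' Deterministic for a fixed seed + template. Returns the record and a
#' truth list recording everything the generator decided (per-PCG start
#' and stop codons, repeat motifs and positions, target composition) so
#' downstream estimates can be checked against known values.
#'
#' @param template a [genome_template()].
#' @param seed integer RNG seed.
#' @param id record identifier.
#' @return list with elements `record` (a `mitogenome`) and `truth`.
#' @examples
#' g <- generate_mitogenome(seed = 42)
#' is_complete(g$record)
#' @export
generate_mitogenome <- function(template = genome_template(), seed = 1,
                                id = "synthetic_mitogenome") {
  stopifnot(inherits(template, "genome_template"))
  set.seed(seed)
  fr <- template$base_fractions
  L <- template$genome_length
  feats <- template$features
  code <- code_info(5)

  genome <- sample_bases(L, fr)
  locked <- logical(L)

  # J-strand position of sense-strand index i within feature f
  sense_jpos <- function(f, i) {
    if (f$strand == "J") as.integer(f$start + i - 1L) else
      as.integer(f$stop - i + 1L)
  }
  write_sense <- function(f, i, bases) {
    jpos <- vapply(i, function(k) sense_jpos(f, k), integer(1))
    jbases <- if (f$strand == "J") bases else unname(.comp_base[bases])
    conflict <- locked[jpos] & genome[jpos] != jbases
    if (any(conflict)) {
      abort(sprintf(
        "template start/stop codons conflict at genome position %d (gene %s)",
        jpos[which(conflict)[1]], f$name))
    }
    genome[jpos] <<- jbases
    locked[jpos] <<- TRUE
  }
  read_sense <- function(f, i) {
    jpos <- vapply(i, function(k) sense_jpos(f, k), integer(1))
    b <- genome[jpos]
    if (f$strand == "J") b else unname(.comp_base[b])
  }

  pcgs <- feats[feature_category(feats$name) == "PCG", ]
  truth_ends <- list()
  # pass 1: stamp start codons and (possibly incomplete) stop codons
  for (r in seq_len(nrow(pcgs))) {
    f <- pcgs[r, ]
    size <- f$stop - f$start + 1L
    start_codon <- if (is.na(f$start_codon) || f$start_codon %in% c("-", "")) "ATG" else f$start_codon
    rem <- size %% 3L
    stop_spec <- if (is.na(f$stop_codon) || f$stop_codon %in% c("-", "")) {
      if (rem == 0L) "TAA" else if (rem == 1L) "T--" else "TA-"
    } else f$stop_codon
    write_sense(f, 1:3, seq_chars(start_codon))
    if (rem == 0L) {
      if (!stop_spec %in% code$stops) {
        abort(sprintf("gene %s: length %% 3 == 0 needs a complete stop codon", f$name))
      }
      write_sense(f, (size - 2L):size, seq_chars(stop_spec))
    } else if (rem == 1L) {
      write_sense(f, size, "T")
    } else {
      write_sense(f, (size - 1L):size, c("T", "A"))
    }
    truth_ends[[f$name]] <- tibble(
      name = f$name, start_codon = start_codon,
      stop_codon = if (rem == 0L) stop_spec else if (rem == 1L) "T--" else "TA-",
      complete = rem == 0L
    )
  }

  # pass 2: fill middle codons, respecting locks, never creating stops.
  # Rejecting stop codons depletes A/T slightly, so the proposal fractions
  # for codon sampling are pre-adjusted (fixed-point iteration on the
  # stop-conditioned marginal) so the realized base composition of coding
  # sequence still matches the template target.
  # N-strand genes are complemented into the J strand, so their sense
  # sequence is sampled from the complement-swapped target to keep the
  # J-strand (reported) composition on target.
  fr_n <- setNames(fr[c("T", "A", "C", "G")], c("A", "T", "G", "C"))
  fr_cod_by_strand <- list(
    J = adjust_for_stop_rejection(fr, code$stops),
    N = adjust_for_stop_rejection(fr_n, code$stops)
  )
  sample_codons <- function(n, fr_cod) {
    m <- matrix(sample(names(fr_cod), 3L * n, replace = TRUE, prob = fr_cod),
                nrow = 3L)
    repeat {
      cods <- paste0(m[1, ], m[2, ], m[3, ])
      bad <- cods %in% code$stops
      if (!any(bad)) return(m)
      m[, bad] <- sample(names(fr_cod), 3L * sum(bad), replace = TRUE,
                         prob = fr_cod)
    }
  }
  for (r in seq_len(nrow(pcgs))) {
    f <- pcgs[r, ]
    size <- f$stop - f$start + 1L
    n_cod <- size %/% 3L
    middle <- if (size %% 3L == 0L) seq_len(n_cod - 2L) + 1L else
      seq_len(n_cod - 1L) + 1L
    if (!length(middle)) next
    jpos_all <- vapply(seq_len(size), function(k) sense_jpos(f, k), integer(1))
    cod_locked <- vapply(middle, function(ci) {
      any(locked[jpos_all[(3L * ci - 2L):(3L * ci)]])
    }, logical(1))
    free_cods <- middle[!cod_locked]
    if (length(free_cods)) {
      m <- sample_codons(length(free_cods), fr_cod_by_strand[[f$strand]])
      idx <- as.vector(vapply(free_cods, function(ci) (3L * ci - 2L):(3L * ci),
                              integer(3)))
      jpos <- jpos_all[idx]
      bases <- as.vector(m)
      genome[jpos] <- if (f$strand == "J") bases else unname(.comp_base[bases])
      locked[jpos] <- TRUE
    }
    for (ci in middle[cod_locked]) {
      ii <- (3L * ci - 2L):(3L * ci)
      jp <- jpos_all[ii]
      fixed <- locked[jp]
      for (try in 1:200) {
        sense <- read_sense(f, ii)
        frs <- fr_cod_by_strand[[f$strand]]
        sense[!fixed] <- sample(names(frs), sum(!fixed), replace = TRUE,
                                prob = frs)
        cod <- paste(sense, collapse = "")
        if (!cod %in% code$stops) break
        if (try == 200L) abort(sprintf(
          "gene %s: cannot avoid a stop codon at codon %d (over-constrained overlap)",
          f$name, ci))
      }
      genome[jp] <- if (f$strand == "J") sense else unname(.comp_base[sense])
      locked[jp] <- TRUE
    }
  }

  # pass 3: control-region repeats (region-relative coordinates)
  ctrl <- feats[feature_category(feats$name) == "control", ]
  truth_repeats <- list()
  if (nrow(ctrl) == 1L && length(template$repeats)) {
    off <- ctrl$start - 1L
    for (rp in template$repeats) {
      motif <- sample_bases(rp$len, fr)
      for (s in rp$starts) {
        genome[off + s + seq_len(rp$len) - 1L] <- motif
      }
      # pin the flanks so the implanted motif is exactly maximal
      lefts <- off + rp$starts - 1L
      rights <- off + rp$starts + rp$len
      tandem <- all(diff(sort(rp$starts)) == rp$len)
      if (tandem) {
        blk <- sort(rp$starts)
        lefts <- off + blk[1] - 1L
        rights <- off + blk[length(blk)] + rp$len
        if (lefts >= 1L && genome[lefts] == motif[rp$len]) {
          genome[lefts] <- sample(setdiff(c("A", "T", "G", "C"), motif[rp$len]), 1)
        }
        if (rights <= L && genome[rights] == motif[1]) {
          genome[rights] <- sample(setdiff(c("A", "T", "G", "C"), motif[1]), 1)
        }
      } else {
        lv <- genome[pmax(lefts, 1L)]
        if (length(unique(lv)) == 1L) {
          genome[lefts[1]] <- sample(setdiff(c("A", "T", "G", "C"), lv[1]), 1)
        }
        rv <- genome[pmin(rights, L)]
        if (length(unique(rv)) == 1L) {
          genome[rights[1]] <- sample(setdiff(c("A", "T", "G", "C"), rv[1]), 1)
        }
      }
      truth_repeats[[length(truth_repeats) + 1L]] <- list(
        motif = paste(motif, collapse = ""), len = rp$len,
        starts = as.integer(rp$starts), tandem = tandem
      )
    }
  }

  record <- mitogenome_record(
    gene_features(feats$name, feats$strand, feats$start, feats$stop),
    sequence = paste(genome, collapse = ""), id = id
  )
  list(
    record = record,
    truth = list(
      seed = seed,
      base_fractions = fr,
      pcg_ends = bind_rows(truth_ends),
      repeats = truth_repeats
    )
  )
}

#' Write a generated genome as GenBank + FASTA + truth JSON
#'
#' Self-describing fixture bundle: the truth parameters travel beside the
#' sequence files.
#'
#' @param sim output of [generate_mitogenome()].
#' @param dir output directory.
#' @return named vector of written paths, invisibly.
#' @export
write_simulated_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sim$record$id
  paths <- c(
    genbank = file.path(dir, paste0(stem, ".gb")),
    fasta = file.path(dir, paste0(stem, ".fasta")),
    truth = file.path(dir, paste0(stem, ".truth.json"))
  )
  write_genbank(sim$record, paths[["genbank"]])
  write_genome_fasta(sim$record, paths[["fasta"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
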