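# Per-gene nucleotide diversity and Nei-Gojobori (1986) Ka/Ks across
# aligned orthologous CDS. The estimator is the classic pathway-counting
# one: per-codon synonymous site fractions averaged between the two
# sequences, observed differences resolved by enumerating all orderings of
# single-base steps with equal weights (orderings passing through stop
# codons excluded), and a Jukes-Cantor multiple-hit correction
# d = -3/4 * log(1 - 4/3 * p) applied to pN and pS.

#' Wrap a set of aligned orthologous coding sequences
#'
#' @param seqs named character vector of aligned, equal-length, in-frame
#'   coding-strand sequences (gaps `-` and N allowed); names are taxon
#'   labels. A Biostrings DNAStringSet is accepted.
#' @param gene gene token the alignment belongs to.
#' @return object of class `ortholog_alignment` (named character vector
#'   with `gene` attribute).
#' @export
ortholog_alignment <- function(seqs, gene = "gene") {
  if (inherits(seqs, "XStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  seqs <- vapply(seqs, norm_seq, character(1), allow_gap = TRUE)
  if (length(seqs) < 2L) abort("an alignment needs at least 2 taxa")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) || any(names(seqs) == "")) {
    abort("taxa labels must be present and unique")
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1L) abort("aligned sequences must have equal length")
  if (L %% 3L != 0L) abort("alignment length must be divisible by 3")
  structure(seqs, gene = gene, class = "ortholog_alignment")
}

#' Read one FASTA alignment per gene from a directory
#'
#' @param dir directory of `<gene>.fasta`/`.fa`/`.fas` codon alignments.
#' @return named list of `ortholog_alignment` objects.
#' @export
read_alignment_dir <- function(dir) {
  paths <- dir(dir, pattern = "\\.(fa|fas|fasta)$", full.names = TRUE)
  if (!length(paths)) abort(sprintf("no FASTA alignments under %s", dir))
  genes <- sub("\\.(fa|fas|fasta)$", "", basename(paths))
  setNames(lapply(seq_along(paths), function(i) {
    ortholog_alignment(Biostrings::readDNAStringSet(paths[i]), genes[i])
  }), genes)
}

#' Nucleotide diversity (Pi) of an alignment
#'
#' Mean pairwise per-site difference over all unordered sequence pairs,
#' with site-wise pairwise deletion: a site enters a pair's comparison only
#' when both sequences carry an unambiguous A/C/G/T there.
#'
#' @param aln an `ortholog_alignment` (or named character vector of aligned
#'   sequences).
#' @return numeric Pi (>= 0).
#' @examples
#' nucleotide_diversity(c(a = "ATGAAA", b = "ATGAAT"))
#' @export
nucleotide_diversity <- function(aln) {
  seqs <- if (inherits(aln, "ortholog_alignment")) unclass(aln) else
    vapply(aln, norm_seq, character(1), allow_gap = TRUE)
  if (length(seqs) < 2L) abort("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L) {
    abort("aligned sequences must have equal length")
  }
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  n <- nrow(m)
  dists <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- valid[i, ] & valid[j, ]
      L <- sum(comp)
      if (L == 0L) {
        dists <- c(dists, NA_real_)
      } else {
        dists <- c(dists, sum(m[i, comp] != m[j, comp]) / L)
      }
    }
  }
  if (all(is.na(dists))) abort("no pair shares a comparable site")
  mean(dists, na.rm = TRUE)
}

# syn/nonsyn step counts for one single-base change codon -> codon
ng_step <- function(from, to, code) {
  if (code[[from]] == code[[to]]) c(syn = 1, nonsyn = 0) else c(syn = 0, nonsyn = 1)
}

# average syn/nonsyn differences for one codon pair over all stop-free
# mutational pathways (equal weighting); if every ordering passes through
# a stop, fall back to averaging over all orderings
ng_codon_diffs <- function(c1, c2, code) {
  pos <- which(seq_chars(c1) != seq_chars(c2))
  k <- length(pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  if (k == 1L) return(ng_step(c1, c2, code))
  orderings <- if (k == 2L) list(pos, rev(pos)) else {
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    lapply(perms, function(p) pos[p])
  }
  walk <- function(ord) {
    cur <- c1
    syn <- 0; nonsyn <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*" && nxt != c2) return(NULL) # pathway through stop
      st <- ng_step(cur, nxt, code)
      syn <- syn + st[["syn"]]; nonsyn <- nonsyn + st[["nonsyn"]]
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  res <- purrr::compact(lapply(orderings, walk))
  if (!length(res)) {
    res <- lapply(orderings, function(ord) {
      cur <- c1; syn <- 0; nonsyn <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        st <- ng_step(cur, nxt, code)
        syn <- syn + st[["syn"]]; nonsyn <- nonsyn + st[["nonsyn"]]
        cur <- nxt
      }
      c(syn = syn, nonsyn = nonsyn)
    })
  }
  colMeans(do.call(rbind, res))
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p == 0) return(0)
  if (p >= 3 / 4) {
    abort(sprintf(
      "substitution proportion %.3f >= 0.75: Jukes-Cantor correction undefined (saturation)", p))
  }
  -3 / 4 * log(1 - 4 / 3 * p)
}

#' Nei-Gojobori Ka/Ks between two aligned coding sequences
#'
#' Codons containing a gap or N in either sequence, and codons that are
#' stop codons in either sequence, are skipped (codon-wise complete
#' deletion). `omega` is `NA` (undefined), not infinite, when `ks = 0`.
#'
#' @param seq_a,seq_b aligned, equal-length, in-frame coding sequences.
#' @param code_id NCBI genetic code id (default 5).
#' @return one-row tibble: `ka`, `ks`, `omega`, `N`, `S` (site counts,
#'   `N + S` = 3 x compared codons), `pn`, `ps` (raw proportions), `nd`,
#'   `sd` (difference counts), `n_codons`.
#' @examples
#' # one synonymous Leu difference (UUA -> CUA) across four codons
#' nei_gojobori("ATGTTAGCAACC", "ATGCTAGCAACC")
#' @export
nei_gojobori <- function(seq_a, seq_b, code_id = 5) {
  seq_a <- norm_seq(seq_a, allow_gap = TRUE)
  seq_b <- norm_seq(seq_b, allow_gap = TRUE)
  if (nchar(seq_a) != nchar(seq_b)) abort("sequences must be aligned (equal length)")
  if (nchar(seq_a) %% 3L != 0L) abort("alignment length must be divisible by 3")
  info <- code_info(code_id)
  code <- info$code
  ca <- seq_codons(seq_a)
  cb <- seq_codons(seq_b)
  clean <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  keep <- clean
  keep[clean] <- !(ca[clean] %in% info$stops) & !(cb[clean] %in% info$stops)
  ca <- ca[keep]; cb <- cb[keep]
  n_codons <- length(ca)
  if (n_codons == 0L) abort("no comparable codons after filtering")

  S <- sum((info$ng_sites[ca] + info$ng_sites[cb]) / 2)
  N <- 3 * n_codons - S
  diffs <- which(ca != cb)
  sd_nd <- c(syn = 0, nonsyn = 0)
  for (i in diffs) {
    sd_nd <- sd_nd + ng_codon_diffs(ca[i], cb[i], code)
  }
  ps <- if (S > 0) sd_nd[["syn"]] / S else NA_real_
  pn <- if (N > 0) sd_nd[["nonsyn"]] / N else NA_real_
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  omega <- if (!is.na(ks) && ks > 0 && !is.na(ka)) ka / ks else NA_real_
  tibble(ka = ka, ks = ks, omega = omega, N = N, S = S,
         pn = pn, ps = ps, nd = sd_nd[["nonsyn"]], sd = sd_nd[["syn"]],
         n_codons = n_codons)
}

#' Divergence panel across a set of per-gene ortholog alignments
#'
#' One row per gene with Pi and the mean pairwise Nei-Gojobori Ka, Ks and
#' Ka/Ks over all unordered taxon pairs (pairs with undefined omega are
#' dropped from the omega mean and counted in `n_pairs_omega_na`), plus
#' conservation ranks (rank 1 = lowest Pi / lowest omega = most conserved).
#'
#' @param alignments named list of `ortholog_alignment` objects (names are
#'   gene tokens; an unnamed list uses each alignment's `gene` attribute).
#' @param code_id NCBI genetic code id (default 5).
#' @return tibble: gene, n_taxa, n_pairs, pi, ka, ks, omega,
#'   n_pairs_omega_na, pi_rank, omega_rank.
#' @export
gene_panel <- function(alignments, code_id = 5) {
  if (!length(alignments)) abort("empty alignment list")
  if (is.null(names(alignments))) {
    names(alignments) <- vapply(alignments, function(a) attr(a, "gene"),
                                character(1))
  }
  rows <- imap(alignments, function(aln, gene) {
    if (!inherits(aln, "ortholog_alignment")) aln <- ortholog_alignment(aln, gene)
    taxa <- names(aln)
    n <- length(taxa)
    pairs <- utils::combn(n, 2, simplify = FALSE)
    est <- purrr::map_dfr(pairs, function(p) {
      nei_gojobori(aln[[p[1]]], aln[[p[2]]], code_id)
    })
    tibble(
      gene = gene, n_taxa = n, n_pairs = length(pairs),
      pi = nucleotide_diversity(aln),
      ka = mean(est$ka, na.rm = TRUE),
      ks = mean(est$ks, na.rm = TRUE),
      omega = if (all(is.na(est$omega))) NA_real_ else mean(est$omega, na.rm = TRUE),
      n_pairs_omega_na = sum(is.na(est$omega))
    )
  })
  bind_rows(rows) |>
    mutate(pi_rank = rank(.data$pi, ties.method = "min"),
           omega_rank = rank(.data$omega, ties.method = "min",
                             na.last = "keep"))
}
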