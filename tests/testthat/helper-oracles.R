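# Independent brute-force oracles. These deliberately re-derive each
# statistic from its definition with naive code (recursion, exhaustive
# scans), sharing nothing with the package implementations they check.

oracle_code <- Biostrings::getGeneticCode("5")
oracle_stops <- names(oracle_code)[oracle_code == "*"]

# --- Nei-Gojobori -----------------------------------------------------------

# synonymous site count of one codon: per position, fraction of the
# non-stop single-base changes that preserve the amino acid
oracle_syn_sites <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    syn <- 0
    valid <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      alt <- paste0(substr(codon, 1, pos - 1), b, substr(codon, pos + 1, 3))
      if (oracle_code[[alt]] == "*") next
      valid <- valid + 1
      if (oracle_code[[alt]] == oracle_code[[codon]]) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# recursive enumeration of all mutational pathways between two codons;
# returns a data frame of (syn, nonsyn) for every stop-free pathway (or,
# if none is stop-free, for every pathway)
oracle_pathways <- function(c1, c2, forbid_stops = TRUE) {
  if (c1 == c2) return(data.frame(syn = 0, nonsyn = 0))
  out <- list()
  for (pos in 1:3) {
    if (substr(c1, pos, pos) == substr(c2, pos, pos)) next
    nxt <- c1
    substr(nxt, pos, pos) <- substr(c2, pos, pos)
    if (forbid_stops && nxt != c2 && oracle_code[[nxt]] == "*") next
    step_syn <- as.numeric(oracle_code[[c1]] == oracle_code[[nxt]])
    rest <- oracle_pathways(nxt, c2, forbid_stops)
    if (nrow(rest) == 0) next
    out[[length(out) + 1]] <- data.frame(syn = rest$syn + step_syn,
                                         nonsyn = rest$nonsyn + (1 - step_syn))
  }
  if (!length(out)) return(data.frame(syn = numeric(0), nonsyn = numeric(0)))
  do.call(rbind, out)
}

oracle_nei_gojobori <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  keep <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
    !(ca %in% oracle_stops) & !(cb %in% oracle_stops)
  ca <- ca[keep]; cb <- cb[keep]
  S <- sum(vapply(ca, oracle_syn_sites, numeric(1)) +
             vapply(cb, oracle_syn_sites, numeric(1))) / 2
  N <- 3 * length(ca) - S
  sd <- 0; nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    paths <- oracle_pathways(ca[i], cb[i])
    if (nrow(paths) == 0) paths <- oracle_pathways(ca[i], cb[i], forbid_stops = FALSE)
    sd <- sd + mean(paths$syn)
    nd <- nd + mean(paths$nonsyn)
  }
  ps <- sd / S
  pn <- nd / N
  jc <- function(p) {
    if (p == 0) return(0)
    if (p >= 0.75) return(NaN)
    -0.75 * log(1 - 4 * p / 3)
  }
  list(S = S, N = N, sd = sd, nd = nd, ps = ps, pn = pn,
       ks = jc(ps), ka = jc(pn))
}

# --- nucleotide diversity ---------------------------------------------------

oracle_pi <- function(seqs) {
  n <- length(seqs)
  mat <- sapply(seqs, function(s) strsplit(s, "")[[1]])
  total <- 0
  npairs <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[, i] %in% c("A", "C", "G", "T") &
        mat[, j] %in% c("A", "C", "G", "T")
      total <- total + sum(mat[ok, i] != mat[ok, j]) / sum(ok)
      npairs <- npairs + 1
    }
  }
  total / npairs
}

# --- repeats ----------------------------------------------------------------

# quadratic all-substrings scan for maximal repeated substrings of length
# in [min_len, max_len], with the same shifted-subset containment
# suppression rule, expressed naively
oracle_repeats <- function(region, min_len, max_len = nchar(region) - 1) {
  n <- nchar(region)
  found <- list()
  for (L in seq(min(max_len, n - 1), min_len, by = -1)) {
    starts <- 1:(n - L + 1)
    subs <- substring(region, starts, starts + L - 1)
    for (m in unique(subs[duplicated(subs)])) {
      occ <- starts[subs == m]
      lefts <- ifelse(occ > 1, substring(region, occ - 1, occ - 1), "")
      rights <- ifelse(occ + L <= n, substring(region, occ + L, occ + L), "")
      left_max <- length(unique(lefts)) > 1 || any(lefts == "")
      right_max <- length(unique(rights)) > 1 || any(rights == "")
      if (!left_max || !right_max) next
      contained <- FALSE
      for (K in found) {
        if (nchar(K$motif) <= L) next
        for (off in 0:(nchar(K$motif) - L)) {
          if (substr(K$motif, off + 1, off + L) == m &&
              setequal(occ, K$occ + off)) {
            contained <- TRUE
            break
          }
        }
        if (contained) break
      }
      if (!contained) found[[length(found) + 1]] <- list(motif = m, occ = occ)
    }
  }
  found
}

# canonical string form of a repeat set, for set comparison
repeat_key <- function(motifs, positions) {
  sort(paste0(motifs, "@", sapply(positions, paste, collapse = ",")))
}
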