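# Exact repeated-motif detection for the A+T-rich control region, via a
# suffix-array / LCP scan: every maximal exact repeat (extendable neither
# left nor right without losing occurrences) of length >= min_len is
# reported once with all copy positions. Approximate repeats are out of
# scope; the default min_len of 9 bp reflects the shortest tandem unit
# typically reported for termite control regions.

#' Find exact repeated motifs in a nucleotide region
#'
#' @param region nucleotide string (the control region, usually).
#' @param min_len minimum motif length in bp (>= 2; default 9).
#' @param collapse_periodic collapse self-overlapping periodic repeats
#'   (occurrence spacing smaller than the motif, e.g. homopolymer runs or
#'   microsatellites) into tandem arrays of one period, truncating
#'   fractional trailing copies (default TRUE). With FALSE such repeats
#'   are reported verbatim as maximal repeats with overlapping copies.
#' @return tibble of hits: `motif`, `motif_len`, `positions` (list column
#'   of 1-based region-relative copy starts), `copy_number`, `tandem`
#'   (copies abut exactly), `identity` (always 1 in exact mode), ordered by
#'   decreasing motif length. A self-overlapping periodic repeat is
#'   collapsed to its tandem array: unit = one period, fractional trailing
#'   copies truncated.
#' @examples
#' find_repeats("GGCCATATATATATGGCC", min_len = 4) # an AT tandem array
#' @export
find_repeats <- function(region, min_len = 9, collapse_periodic = TRUE) {
  region <- norm_seq(region)
  n <- nchar(region)
  if (min_len < 2) abort("min_len must be >= 2")
  if (n < min_len) abort("region shorter than min_len")

  suffixes <- substring(region, seq_len(n), n)
  sa <- order(suffixes, method = "radix")
  sorted <- suffixes[sa]
  lcp_pair <- function(a, b) {
    k <- min(nchar(a), nchar(b))
    if (k == 0L) return(0L)
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    neq <- which(av[seq_len(k)] != bv[seq_len(k)])
    if (length(neq)) neq[1] - 1L else k
  }
  lcp <- c(0L, vapply(2:max(n, 2), function(i) {
    if (i > n) 0L else lcp_pair(sorted[i - 1], sorted[i])
  }, integer(1))[seq_len(max(0, n - 1))])

  # candidate motifs: every lcp value >= min_len names a repeated prefix
  cand <- unique(unlist(lapply(which(lcp >= min_len), function(i) {
    substr(sorted[i], 1L, lcp[i])
  })))
  if (!length(cand)) {
    return(tibble(motif = character(0), motif_len = integer(0),
                  positions = list(), copy_number = integer(0),
                  tandem = logical(0), identity = numeric(0)))
  }

  occurrences <- function(motif) {
    L <- nchar(motif)
    starts <- seq_len(n - L + 1L)
    sort(starts[substring(region, starts, starts + L - 1L) == motif])
  }
  left_char <- function(p) if (p > 1L) substr(region, p - 1L, p - 1L) else ""
  right_char <- function(p, L) {
    if (p + L <= n) substr(region, p + L, p + L) else ""
  }

  hits <- list()
  for (m in cand) {
    L <- nchar(m)
    occ <- occurrences(m)
    if (length(occ) < 2L) next
    rc <- vapply(occ, right_char, character(1), L = L)
    lc <- vapply(occ, left_char, character(1))
    right_max <- length(unique(rc)) > 1L || any(rc == "")
    left_max <- length(unique(lc)) > 1L || any(lc == "")
    if (right_max && left_max) {
      hits[[length(hits) + 1L]] <- list(motif = m, len = L, occ = occ)
    }
  }
  if (!length(hits)) {
    return(tibble(motif = character(0), motif_len = integer(0),
                  positions = list(), copy_number = integer(0),
                  tandem = logical(0), identity = numeric(0)))
  }

  # suppress a hit fully contained (same occurrence set, shifted) in a
  # longer reported hit
  lens <- vapply(hits, function(h) h$len, integer(1))
  hits <- hits[order(-lens)]
  kept <- list()
  for (h in hits) {
    contained <- any(vapply(kept, function(K) {
      if (K$len <= h$len) return(FALSE)
      offs <- seq_len(K$len - h$len + 1L) - 1L
      any(vapply(offs, function(o) {
        substr(K$motif, o + 1L, o + h$len) == h$motif &&
          setequal(h$occ, K$occ + o)
      }, logical(1)))
    }, logical(1)))
    if (!contained) kept[[length(kept) + 1L]] <- h
  }

  rows <- lapply(kept, function(h) {
    occ <- h$occ
    d <- diff(occ)
    if (collapse_periodic && length(d) && any(d < h$len)) {
      # self-overlapping periodic repeat -> tandem array of one period
      p <- min(d)
      span <- max(occ) + h$len - min(occ)
      cn <- span %/% p
      tibble(
        motif = substr(region, min(occ), min(occ) + p - 1L),
        motif_len = p,
        positions = list(min(occ) + p * (seq_len(cn) - 1L)),
        copy_number = cn,
        tandem = TRUE, identity = 1
      )
    } else {
      tibble(
        motif = h$motif, motif_len = h$len, positions = list(occ),
        copy_number = length(occ),
        tandem = length(d) > 0 && all(d == h$len), identity = 1
      )
    }
  })
  bind_rows(rows) |>
    dplyr::distinct(.data$motif, .data$motif_len, .data$copy_number,
                    .data$tandem, .keep_all = TRUE) |>
    arrange(dplyr::desc(.data$motif_len), purrr::map_int(.data$positions, 1))
}
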