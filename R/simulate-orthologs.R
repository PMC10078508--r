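# Ortholog-divergence simulator: a rejection sampler over single-base
# proposals, not a codon-model matrix exponential. Each taxon evolves
# independently from the root CDS; proposals creating stop codons are
# rejected outright, synonymous proposals are accepted with relative
# probability 1 and nonsynonymous ones with relative probability omega, so
# the realized nonsynonymous/synonymous rate ratio per opportunity is
# exactly the omega target. Sufficient for estimator-recovery tests and
# fully specifiable.

.transitions <- c(A = "G", G = "A", C = "T", T = "C")

#' Specify a divergence scenario
#'
#' @param n_taxa number of tip sequences to evolve (>= 2).
#' @param omega target nonsynonymous/synonymous rate ratio (>= 0; 0 is the
#'   pure-purifying limit where only synonymous changes fix).
#' @param subs_per_codon expected accepted substitutions per codon on each
#'   root-to-tip path (branch-length proxy; default 0.2, a moderate
#'   congeneric-mitogenome divergence).
#' @param tstv transition/transversion proposal ratio (default 1, matching
#'   the equal-weighting assumption of the Nei-Gojobori estimator).
#' @param seed optional RNG seed applied by [simulate_orthologs()].
#' @return list of class `divergence_scenario`.
#' @export
divergence_scenario <- function(n_taxa = 6, omega = 0.5,
                                subs_per_codon = 0.2, tstv = 1,
                                seed = NULL) {
  if (omega < 0) abort("omega must be >= 0")
  stopifnot(n_taxa >= 2, subs_per_codon >= 0, tstv > 0)
  structure(list(n_taxa = n_taxa, omega = omega,
                 subs_per_codon = subs_per_codon, tstv = tstv, seed = seed),
            class = "divergence_scenario")
}

#' Evolve an ortholog alignment from a root CDS
#'
#' @param cds in-frame, stop-free root coding sequence (length divisible
#'   by 3).
#' @param scenario a [divergence_scenario()].
#' @param code_id NCBI genetic code id (default 5).
#' @return an `ortholog_alignment` (taxa `t1..tN`) with attribute `truth`:
#'   tibble of realized accepted synonymous/nonsynonymous change counts
#'   per taxon.
#' @examples
#' aln <- simulate_orthologs(strrep("ATGGCTGCA", 20),
#'                           divergence_scenario(n_taxa = 2, omega = 1,
#'                                               seed = 7))
#' @export
simulate_orthologs <- function(cds, scenario = divergence_scenario(),
                               code_id = 5) {
  stopifnot(inherits(scenario, "divergence_scenario"))
  cds <- norm_seq(cds)
  if (nchar(cds) %% 3L != 0L) abort("root CDS must be in frame (length %% 3 == 0)")
  info <- code_info(code_id)
  root_codons <- seq_codons(cds)
  if (any(root_codons %in% info$stops)) abort("root CDS contains a stop codon")
  if (!is.null(scenario$seed)) set.seed(scenario$seed)

  n_cod <- length(root_codons)
  n_target <- round(scenario$subs_per_codon * n_cod)
  bases <- c("A", "C", "G", "T")
  p_nonsyn <- min(1, scenario$omega)
  p_syn <- if (scenario$omega > 1) 1 / scenario$omega else 1

  evolve_one <- function() {
    chars <- seq_chars(cds)
    nsites <- length(chars)
    accepted_syn <- 0L
    accepted_nonsyn <- 0L
    guard <- 0L
    while (accepted_syn + accepted_nonsyn < n_target) {
      guard <- guard + 1L
      if (guard > 2000L * max(n_target, 1L)) {
        abort("mutation sampler stalled: scenario admits too few acceptable changes")
      }
      site <- sample.int(nsites, 1L)
      cur <- chars[site]
      ts <- .transitions[[cur]]
      tv <- setdiff(bases, c(cur, ts))
      new <- sample(c(ts, tv), 1L,
                    prob = c(scenario$tstv, 1, 1) / (scenario$tstv + 2))
      ci <- (site - 1L) %/% 3L + 1L
      ii <- (3L * ci - 2L):(3L * ci)
      old_codon <- paste(chars[ii], collapse = "")
      new_chars <- chars[ii]
      new_chars[site - 3L * (ci - 1L)] <- new
      new_codon <- paste(new_chars, collapse = "")
      if (info$code[[new_codon]] == "*") next
      syn <- info$code[[new_codon]] == info$code[[old_codon]]
      p <- if (syn) p_syn else p_nonsyn
      if (p < 1 && stats::runif(1) > p) next
      chars[site] <- new
      if (syn) accepted_syn <- accepted_syn + 1L else
        accepted_nonsyn <- accepted_nonsyn + 1L
    }
    list(seq = paste(chars, collapse = ""),
         syn = accepted_syn, nonsyn = accepted_nonsyn)
  }

  tips <- lapply(seq_len(scenario$n_taxa), function(i) evolve_one())
  seqs <- setNames(vapply(tips, `[[`, character(1), "seq"),
                   paste0("t", seq_len(scenario$n_taxa)))
  aln <- ortholog_alignment(seqs, gene = "simulated")
  attr(aln, "truth") <- tibble(
    taxon = names(seqs),
    accepted_syn = vapply(tips, `[[`, integer(1), "syn"),
    accepted_nonsyn = vapply(tips, `[[`, integer(1), "nonsyn"),
    omega_target = scenario$omega,
    subs_per_codon = scenario$subs_per_codon
  )
  aln
}
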