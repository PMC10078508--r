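# Nucleotide diversity and Nei-Gojobori Ka/Ks.

test_that("pi matches hand-enumerated pairwise differences", {
  expect_equal(nucleotide_diversity(c(a = "ATGATG", b = "ATGATG")), 0)
  # 3 sequences, L = 10, pairwise diffs {1, 2, 3} -> (0.1+0.2+0.3)/3
  s1 <- "AAAAAAAAAA"
  s2 <- "TAAAAAAAAA"  # 1 diff vs s1
  s3 <- "TTAAAAAAAT"  # 3 diffs vs s1, 2 vs s2
  aln <- c(x = s1, y = s2, z = s3)
  expect_equal(nucleotide_diversity(aln), 0.2)
  expect_equal(nucleotide_diversity(aln), oracle_pi(aln))
})

test_that("pi is invariant to sequence order and uses pairwise deletion", {
  set.seed(3)
  seqs <- setNames(vapply(1:4, function(i) random_region(60), character(1)),
                   letters[1:4])
  p1 <- nucleotide_diversity(seqs)
  p2 <- nucleotide_diversity(rev(seqs))
  expect_equal(p1, p2)
  expect_equal(p1, oracle_pi(seqs))
  # gaps/N excluded site-wise per pair
  g <- c(a = "ATGAT-", b = "ATGATN", c = "TTGATT")
  expect_equal(nucleotide_diversity(g), oracle_pi(g))
})

test_that("nei_gojobori edge behaviour: identical, pure-syn, pure-nonsyn", {
  cds <- random_cds(30, seed = 5)
  same <- nei_gojobori(cds, cds)
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)
  expect_true(is.na(same$omega))
  expect_equal(same$N + same$S, 3 * 30)

  # only synonymous differences (Leu UUA <-> UUG) -> ka = 0 exactly
  a <- strrep("TTA", 20)
  b <- paste0(strrep("TTA", 18), "TTGTTG")
  est <- nei_gojobori(a, b)
  expect_equal(est$ka, 0)
  expect_gt(est$ks, 0)
  # only nonsynonymous (Leu UUA -> Ser UCA) -> ks = 0 exactly
  c1 <- paste0(strrep("TTA", 18), "TCATCA")
  est2 <- nei_gojobori(a, c1)
  expect_equal(est2$ks, 0)
  expect_gt(est2$ka, 0)
  expect_true(is.na(est2$omega))
})

test_that("nei_gojobori is symmetric and skips gapped/stop codons", {
  a <- random_cds(20, seed = 11)
  aln <- simulate_orthologs(a, divergence_scenario(n_taxa = 2, omega = 0.8,
                                                   subs_per_codon = 0.3,
                                                   seed = 2))
  e1 <- nei_gojobori(aln[[1]], aln[[2]])
  e2 <- nei_gojobori(aln[[2]], aln[[1]])
  expect_equal(e1, e2)
  # codons with gaps or N are dropped from sites and differences
  g1 <- "ATG---TTAAAN"
  g2 <- "ATGTTATCAAAT"
  eg <- nei_gojobori(g1, g2)
  expect_equal(eg$n_codons, 2L)
  expect_equal(eg$N + eg$S, 6)
  expect_equal(eg$nd, 1)  # the one comparable difference is nonsynonymous
  expect_equal(eg$sd, 0)
})

test_that("nei_gojobori equals the brute-force pathway oracle", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(1:10, 1)
    a <- random_cds(n)
    # mutate up to 2n random positions to exercise 1-, 2- and 3-step codons
    chars <- strsplit(a, "")[[1]]
    nmut <- sample(1:max(1, 2 * n %/% 2), 1)
    pos <- sample(length(chars), min(nmut, length(chars)))
    chars[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    b <- paste(chars, collapse = "")
    # keep the pair stop-free for a clean comparison
    bc <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    if (any(bc %in% oracle_stops)) next
    want <- oracle_nei_gojobori(a, b)
    if (want$ps >= 0.75 || want$pn >= 0.75) {
      # saturated pair: the package must refuse the correction
      expect_error(nei_gojobori(a, b), "saturation")
      next
    }
    got <- nei_gojobori(a, b)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$sd, want$sd, tolerance = 1e-12)
    expect_equal(got$nd, want$nd, tolerance = 1e-12)
    expect_equal(got$ks, want$ks, tolerance = 1e-12)
    expect_equal(got$ka, want$ka, tolerance = 1e-12)
  }
})

test_that("saturated proportions raise an explicit error", {
  a <- strrep("TTA", 10)
  b <- strrep("TTG", 10)  # every codon differs synonymously: ps near 1
  expect_error(nei_gojobori(a, b), "saturation")
})

test_that("gene_panel ranks genes and preserves simulated omega order", {
  cds <- random_cds(200, seed = 31)
  targets <- c(gene_a = 0.05, gene_b = 0.3, gene_c = 0.5)
  alns <- purrr::imap(targets, function(om, g) {
    simulate_orthologs(cds, divergence_scenario(n_taxa = 4, omega = om,
                                                subs_per_codon = 0.25,
                                                seed = 400 + round(100 * om)))
  })
  panel <- gene_panel(alns)
  expect_equal(panel$gene, names(targets))
  expect_equal(order(panel$omega), order(targets))
  expect_true(all(panel$pi > 0))
  # identical alignments -> all pi zero
  same <- list(g1 = ortholog_alignment(c(a = cds, b = cds)))
  expect_equal(gene_panel(same)$pi, 0)
  expect_error(gene_panel(list()), "empty")
})
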