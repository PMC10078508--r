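# Synthetic genome and ortholog-divergence generators.

test_that("generation is deterministic and yields a complete 37-gene record", {
  g1 <- generate_mitogenome(seed = 42)
  g2 <- generate_mitogenome(seed = 42)
  expect_identical(g1$record$sequence, g2$record$sequence)
  expect_identical(g1$truth, g2$truth)
  expect_false(identical(g1$record$sequence,
                         generate_mitogenome(seed = 43)$record$sequence))
  rec <- g1$record
  expect_true(is_complete(rec))
  expect_equal(nrow(rec$features), 38L)
  expect_equal(rec$length, 15655L)
})

test_that("generated PCGs honour the truth record ends and are stop-free", {
  g <- generate_mitogenome(seed = 7)
  ends <- pcg_end_table(g$record)
  truth <- g$truth$pcg_ends
  merged <- dplyr::left_join(ends, truth, by = "name",
                             suffix = c("", "_truth"))
  expect_equal(merged$start_codon, merged$start_codon_truth)
  expect_equal(merged$stop_codon, merged$stop_codon_truth)
  expect_equal(merged$complete, merged$complete_truth)
  # no internal stops under the mito code, even across gene overlaps
  code <- genetic_code(5)
  for (gname in truth$name) {
    cds <- feature_sequence(g$record, gname)
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                        seq(3, nchar(cds), 3))
    n <- length(codons)
    internal <- codons[-n][code[codons[-n]] == "*"]
    expect_length(internal, 0)
  }
})

test_that("layout conservation holds on generated genomes", {
  for (seed in c(3, 14)) {
    g <- generate_mitogenome(seed = seed)
    lay <- layout_report(g$record)
    expect_true(lay$summary$conservation_ok)
  }
})

test_that("implanted control-region repeats are recovered exactly", {
  g <- generate_mitogenome(seed = 42)
  dl <- feature_sequence(g$record, "d-loop")
  hits <- find_repeats(dl, 9)
  long_truth <- g$truth$repeats[[1]]
  tand_truth <- g$truth$repeats[[2]]
  long <- hits[hits$motif == long_truth$motif, ]
  expect_equal(nrow(long), 1L)
  expect_equal(long$positions[[1]], long_truth$starts)
  expect_false(long$tandem)
  tand <- hits[hits$motif == tand_truth$motif, ]
  expect_equal(nrow(tand), 1L)
  expect_true(tand$tandem)
  expect_equal(tand$positions[[1]], tand_truth$starts)
})

test_that("genome round-trips through the simulated-fixture bundle", {
  d <- withr::local_tempdir()
  sim <- generate_mitogenome(seed = 9, id = "roundtrip")
  paths <- write_simulated_genome(sim, d)
  expect_true(all(file.exists(paths)))
  back <- read_genbank(paths[["genbank"]])
  expect_equal(back$sequence, sim$record$sequence)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$seed, 9)
})

test_that("omega = 0 fixes only synonymous changes; zero branch length is a no-op", {
  cds <- random_cds(80, seed = 61)
  aln <- simulate_orthologs(cds, divergence_scenario(n_taxa = 2, omega = 0,
                                                     subs_per_codon = 0.3,
                                                     seed = 4))
  truth <- attr(aln, "truth")
  expect_equal(sum(truth$accepted_nonsyn), 0L)
  est <- nei_gojobori(aln[[1]], aln[[2]])
  expect_equal(est$ka, 0)
  expect_error(divergence_scenario(omega = -0.5), "omega")

  still <- simulate_orthologs(cds, divergence_scenario(n_taxa = 3,
                                                       subs_per_codon = 0,
                                                       seed = 5))
  expect_equal(unname(as.character(still)), rep(cds, 3))
  expect_equal(nucleotide_diversity(still), 0)
})

test_that("estimated omega converges to the simulated target", {
  cds <- random_cds(300, seed = 71)
  ests <- vapply(1:8, function(s) {
    aln <- simulate_orthologs(cds, divergence_scenario(n_taxa = 2, omega = 1,
                                                       subs_per_codon = 0.2,
                                                       seed = s))
    nei_gojobori(aln[[1]], aln[[2]])$omega
  }, numeric(1))
  expect_gt(mean(ests), 0.8)
  expect_lt(mean(ests), 1.2)
})
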