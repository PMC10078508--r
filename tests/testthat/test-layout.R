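# Circular layout arithmetic: sizes, intergenic distances, strand
# tallies, and the coverage-conservation identity.

test_that("feature lengths re-derive every printed size of the termite table", {
  rec <- termite_record()
  lay <- layout_report(rec)
  printed_sizes <- c(
    trnI = 65, trnQ = 69, trnM = 66, nad2 = 1002, trnW = 67, trnC = 66,
    trnY = 68, cox1 = 1545, trnL2 = 67, cox2 = 667, trnK = 71, trnD = 67,
    atp8 = 159, atp6 = 681, cox3 = 789, trnG = 64, nad3 = 354, trnA = 62,
    trnR = 65, trnN = 67, trnS1 = 67, trnE = 63, trnF = 66, nad5 = 1726,
    trnH = 64, nad4 = 1338, nad4l = 288, trnT = 64, trnP = 65, nad6 = 477,
    cytb = 1134, trnS2 = 73, nad1 = 939, trnL1 = 68, rrnL = 1366,
    trnV = 68, rrnS = 805, `d-loop` = 871
  )
  got <- setNames(lay$features$size, lay$features$name)
  expect_equal(got[names(printed_sizes)], printed_sizes)
})

test_that("feature_length handles plain, single-base and origin-wrapping features", {
  expect_equal(feature_length(1437, 2981, 15655), 1545L)
  expect_equal(feature_length(3886, 4044, 15655), 159L)
  expect_equal(feature_length(100, 100, 15655), 1L)
  # wrap: last 10 bases plus first 5
  expect_equal(feature_length(15646, 5, 15655), 15L)
  expect_error(feature_length(0, 10, 100), "outside")
  expect_error(feature_length(5, 101, 100), "outside")
})

test_that("intergenic distances are signed gaps, including across the origin", {
  expect_equal(intergenic(11573, 11597), 23L)  # longest spacer of the table
  expect_equal(intergenic(9461, 9455), -7L)    # deepest PCG-PCG overlap
  expect_equal(intergenic(100, 101), 0L)       # abutting genes
  expect_equal(intergenic(15655, 1, 15655, wrap = TRUE), 0L)
  expect_equal(intergenic(15650, 3, 15655, wrap = TRUE), 7L)
})

test_that("layout summary matches the termite genome architecture", {
  lay <- layout_report(termite_record())
  s <- lay$summary
  expect_equal(s$genome_length, 15655L)
  expect_equal(s$j_strand_genes, 23L)
  expect_equal(s$n_strand_genes, 14L)
  tall <- lay$strand_tallies
  expect_equal(tall$n_genes[tall$strand == "N" & tall$category == "rRNA"], 2L)
  expect_equal(tall$n_genes[tall$strand == "J" & tall$category == "PCG"], 9L)
  expect_equal(tall$n_genes[tall$strand == "J" & tall$category == "tRNA"], 14L)
  expect_equal(s$longest_spacer_bp, 23L)
  expect_equal(s$longest_spacer_pair, "trnS2-nad1")
  # coordinate-derived views: trnW/trnC is the deepest non-rRNA overlap,
  # and the two soft rRNA boundaries are tallied separately
  expect_equal(s$n_overlaps, 7L)
  expect_equal(s$n_overlaps_rrna, 2L)
  expect_equal(s$longest_overlap_bp, 8L)
  pair_gap <- lay$pairs$gap[lay$pairs$upstream == "nad4"]
  expect_equal(pair_gap, -7L)
  expect_true(s$conservation_ok)
})

test_that("conservation identity holds on random circular layouts", {
  for (seed in 1:30) {
    ly <- random_layout(n_feats = sample(5:20, 1), seed = seed)
    lay <- layout_report(ly$features, genome_length = ly$genome_length)
    expect_equal(sum(lay$features$size) + sum(lay$pairs$gap),
                 ly$genome_length)
    expect_true(all(lay$features$size >= 1))
  }
})

test_that("layout_report rejects unsorted or out-of-range features", {
  f <- tibble::tibble(name = c("trnB", "trnA"), category = "tRNA",
                      strand = "J", start = c(10L, 1L), stop = c(20L, 5L))
  expect_error(layout_report(f, genome_length = 100), "sorted")
  g <- gene_features(c("trnA", "trnB"), c("J", "J"), c(1, 50), c(5, 90))
  expect_error(layout_report(g, genome_length = 60), "outside")
})

test_that("classify_ends recognises complete and truncated stops", {
  # cox2-style: 667 bp, remainder 1, trailing T
  cds1 <- paste0("ATA", substr(random_cds(222, seed = 1), 4, 666), "T")
  e1 <- classify_ends(cds1)
  expect_equal(e1$start_codon, "ATA")
  expect_equal(e1$stop_codon, "T--")
  expect_false(e1$complete)
  # nad4-style: GTG start, complete TAG stop, 1338 bp
  cds2 <- paste0("GTG", substr(random_cds(445, seed = 2), 4, 1335), "TAG")
  e2 <- classify_ends(cds2)
  expect_equal(e2$start_codon, "GTG")
  expect_equal(e2$stop_codon, "TAG")
  expect_true(e2$complete)
  # minimal CDS
  expect_equal(classify_ends("ATGTAA"),
               tibble::tibble(start_codon = "ATG", stop_codon = "TAA",
                              complete = TRUE))
  # TA- truncation
  expect_equal(classify_ends("ATGAAATA")$stop_codon, "TA-")
  # malformed tails
  expect_error(classify_ends("ATGAAAG"), "malformed")
  expect_error(classify_ends("ATGAAAGG"), "malformed")
  expect_error(classify_ends("ATGAAACCC"), "malformed")
})

test_that("any in-frame CDS ending in TAA/TAG classifies as complete", {
  for (seed in 1:10) {
    stop_codon <- sample(c("TAA", "TAG"), 1)
    cds <- paste0(random_cds(sample(5:60, 1), seed = seed), stop_codon)
    expect_true(classify_ends(cds)$complete)
  }
})
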