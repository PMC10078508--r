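# Supermatrix preparation and the NJ sanity tree.

test_that("strip_stops trims a shared terminal stop and flags internal ones", {
  aln <- ortholog_alignment(c(a = "ATGTTATAA", b = "ATGCTATAG"), "nad3")
  out <- strip_stops(aln)
  expect_equal(nchar(out[[1]]), 6L)
  expect_equal(unclass(out)[["a"]], "ATGTTA")
  # stop-free alignment unchanged
  aln2 <- ortholog_alignment(c(a = "ATGTTA", b = "ATGCTA"))
  expect_equal(unclass(strip_stops(aln2)), unclass(aln2))
  # internal stop names taxon and codon
  bad <- ortholog_alignment(c(a = "ATGTTATTATTATTATTA",
                              b = "ATGTTATTATTATAATTA"))
  expect_error(strip_stops(bad), "taxon 'b' at codon 5")
})

test_that("filter_columns removes gapped codon columns whole", {
  aln <- ortholog_alignment(c(a = "ATGTTAGCA", b = "ATGTTAGCA"))
  expect_equal(unclass(filter_columns(aln)), unclass(aln))
  # one gapped codon in one taxon, strict mode: 3 columns go
  g <- ortholog_alignment(c(a = "ATGTTAGCA", b = "ATG--AGCA"))
  expect_equal(nchar(filter_columns(g)[[1]]), 6L)
  # 5-codon alignment, 2 gapped codon columns -> 9 columns remain
  h <- ortholog_alignment(c(a = "ATGTTAGCAATGGGC",
                            b = "ATG-TAGCAATGG-C",
                            c = "ATGTTAGCAATGGGC"))
  expect_equal(nchar(filter_columns(h)[[1]]), 9L)
  # a tolerant threshold keeps columns below the gap fraction
  expect_equal(nchar(filter_columns(h, max_gap_fraction = 0.5)[[1]]), 15L)
})

test_that("concatenation tiles partitions and fills missing taxa with gaps", {
  a1 <- ortholog_alignment(c(t1 = "ATGTTA", t2 = "ATGCTA"), "cox1")
  a2 <- ortholog_alignment(c(t1 = "ATGAAATTT", t3 = "ATGAAGTTC"), "atp6")
  sm <- concatenate_genes(list(cox1 = a1, atp6 = a2))
  expect_equal(sm$length, 15L)
  # canonical gene order puts atp6 first regardless of list order
  expect_equal(sm$partitions$gene, c("atp6", "cox1"))
  expect_equal(sm$partitions$start, c(1L, 10L))
  expect_equal(sm$partitions$end, c(9L, 15L))
  # tiling invariant
  expect_equal(sm$partitions$start[-1], sm$partitions$end[-2] + 1L)
  expect_equal(dplyr::last(sm$partitions$end), sm$length)
  # gap fill for missing taxon x gene blocks
  expect_equal(sm$aln[["t3"]], paste0("ATGAAGTTC", "------"))
  expect_equal(unique(nchar(sm$aln)), 15L)
  # input order invariance
  sm2 <- concatenate_genes(list(atp6 = a2, cox1 = a1))
  expect_equal(sm2$aln, sm$aln)
  expect_equal(sm2$partitions, sm$partitions)
  # single gene: supermatrix = that alignment
  sm3 <- concatenate_genes(list(cox1 = a1))
  expect_equal(unname(sm3$aln), unname(as.character(a1)))
  expect_error(concatenate_genes(list(cox1 = a1), taxa = c("t1", "t1")),
               "duplicate")
})

test_that("supermatrix files carry both partition dialects", {
  a1 <- ortholog_alignment(c(t1 = "ATGTTA", t2 = "ATGCTA"), "cox1")
  a2 <- ortholog_alignment(c(t1 = "ATGAAA", t2 = "ATGAAG"), "cytb")
  sm <- concatenate_genes(list(a1, a2) |> setNames(c("cox1", "cytb")))
  d <- withr::local_tempdir()
  paths <- write_supermatrix(sm, d)
  expect_true(all(file.exists(paths)))
  expect_equal(readLines(paths[["phylip"]])[1], "2 12")
  expect_equal(readLines(paths[["raxml"]]),
               c("DNA, cox1 = 1-6", "DNA, cytb = 7-12"))
  nex <- readLines(paths[["nexus"]])
  expect_true(any(grepl("charset cox1 = 1-6;", nex)))
})

test_that("NJ recovers the topology behind an additive distance matrix", {
  # distances generated from the tree ((A:2,B:3):1,(C:2,D:4):2); by path sums
  tr <- ape::read.tree(text = "((A:2,B:3):1,(C:2,D:4):2);")
  d <- cophenetic(tr)
  nj <- distance_tree(d)
  expect_equal(sort(nj$tip.label), c("A", "B", "C", "D"))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj)), 0,
               ignore_attr = TRUE)
  # recovered branch lengths reproduce the additive distances
  expect_equal(cophenetic(nj)[rownames(d), colnames(d)], d)
})

test_that("degenerate distance inputs behave", {
  sm <- concatenate_genes(list(g = ortholog_alignment(
    c(a = "ATGTTA", b = "ATGTTA", c = "ATGTTA"), "g")))
  tree <- distance_tree(sm)
  expect_equal(sum(tree$edge.length), 0)
  expect_equal(ape::Ntip(tree), 3L)  # unique unrooted 3-taxon topology
  sm2 <- concatenate_genes(list(g = ortholog_alignment(
    c(a = "ATGTTA", b = "ATGTTC"), "g")))
  expect_error(distance_tree(sm2), "3 taxa")
})

test_that("the full supermatrix path recovers a known 5-taxon topology", {
  root <- random_cds(150, seed = 55)
  alns <- lapply(setNames(c(600, 700, 800), c("cox1", "cytb", "nad2")),
                 function(s) tree_orthologs(root, seed = s))
  alns <- purrr::imap(alns, function(a, g) {
    attr(a, "gene") <- g
    a
  })
  sm <- concatenate_genes(alns)
  expect_equal(sm$length, 3 * 450L)
  tree <- distance_tree(sm, model = "JC")
  rooted <- ape::root(tree, outgroup = "E", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, c("A", "B")))
  expect_true(ape::is.monophyletic(rooted, c("C", "D")))
})
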