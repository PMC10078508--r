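# Shared fixtures, built in code at test time.

table2_path <- function() {
  mitochar_example("cryptotermes_domesticus_features.tsv")
}

termite_record <- function() read_feature_table(table2_path())

# a random in-frame, stop-free CDS of n codons (start ATG, no terminal stop)
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(oracle_code), oracle_stops)
  paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)), collapse = "")
}

# random nucleotide string
random_region <- function(n, seed = NULL,
                          p = c(A = 0.3, T = 0.3, G = 0.2, C = 0.2)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# a random circular coordinate-only layout: n features tiling a genome
# with random spacers (>= 0) and occasional pairwise overlaps
random_layout <- function(n_feats = 12, seed = 1) {
  set.seed(seed)
  sizes <- sample(60:900, n_feats, replace = TRUE)
  gaps <- sample(c(0, 0, 1, 3, 8, 15, -1, -4), n_feats, replace = TRUE)
  # keep overlaps strictly pairwise: an overlap consumes part of the
  # previous feature, so cap it well below both neighbours' sizes
  gaps <- pmax(gaps, -pmin(sizes, c(sizes[-1], sizes[1])) + 10)
  starts <- integer(n_feats)
  stops <- integer(n_feats)
  pos <- 1L
  for (i in seq_len(n_feats)) {
    starts[i] <- pos
    stops[i] <- pos + sizes[i] - 1L
    pos <- stops[i] + gaps[i] + 1L
  }
  genome_length <- stops[n_feats] + sample(0:30, 1)  # trailing wrap spacer
  feats <- gene_features(
    name = sprintf("trn%s", c(LETTERS, letters)[seq_len(n_feats)]),
    strand = sample(c("J", "N"), n_feats, replace = TRUE),
    start = starts, stop = stops
  )
  list(features = feats, genome_length = genome_length)
}

# tiny record with one PCG (J), one tRNA (J), one rRNA (N), one control
# region and known sequences, for composition-class tests
toy_record <- function() {
  pcg <- "ATGTTAGCTTAA"                  # 4 codons incl. TAA stop
  trna <- "ACGTACGTACGTACG"              # 15 bp
  rrna_sense <- "TTTTTTTTGGAACCTTTTTT"   # T-rich on its sense (N) strand
  ctrl <- "ATATATATATGCGC"
  j <- paste0(pcg, trna, revcomp_chr(rrna_sense), ctrl)
  feats <- tibble::tibble(
    name = c("nad2", "trnA", "rrnS", "d-loop"),
    strand = c("J", "J", "N", "J"),
    start = c(1, 13, 28, 48),
    stop = c(12, 27, 47, 61)
  )
  mitogenome_record(feats, sequence = j, id = "toy")
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# hierarchical (tree-based) ortholog simulation: evolve along a fixed
# 5-taxon topology ((A,B),(C,D),E) by chaining the star simulator
tree_orthologs <- function(root, seed, subs = 0.06) {
  sc <- function(n, s) divergence_scenario(n_taxa = n, omega = 0.2,
                                           subs_per_codon = subs, seed = s)
  anc1 <- simulate_orthologs(root, sc(2, seed))[[1]]
  anc2 <- simulate_orthologs(root, sc(2, seed + 100))[[1]]
  ab <- simulate_orthologs(anc1, sc(2, seed + 1))
  cd <- simulate_orthologs(anc2, sc(2, seed + 2))
  e <- simulate_orthologs(root, sc(2, seed + 3))[[1]]
  ortholog_alignment(
    c(A = ab[[1]], B = ab[[2]], C = cd[[1]], D = cd[[2]], E = e),
    gene = "simtree"
  )
}
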