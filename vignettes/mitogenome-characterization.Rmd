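---
title: "Methods: characterizing an insect mitogenome with mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing an insect mitogenome with mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

mitochar computes the standard descriptive battery for annotated insect
mitochondrial genomes. This vignette is the package's account of the
models and conventions behind each statistic, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## Coordinates and the circular layout model

All coordinates are 1-based inclusive positions on the majority (J)
strand — the convention of mitogenome characteristics tables — and both
strands share that one coordinate system. Minority (N) strand features
are stored with `start < stop` and reverse-complemented on extraction,
so a published table can be ingested verbatim even when its N-strand
rows are printed 5'→3' on their own strand (start > stop). A feature
wrapping the circular origin is the one case with `start > stop` after
normalisation; the origin itself is fixed at position 1 (the *trnI*
start in the canonical termite architecture), and the control-region →
*trnI* junction is evaluated as the wrap-around pair.

The signed intergenic distance between adjacent features is
`next.start − prev.stop − 1`; positive values are spacers, negative
values overlaps. For features sorted by start on a circular record this
telescopes to the conservation identity

> Σ feature sizes + Σ signed gaps = genome length,

which `layout_report()` verifies on every run and the tests verify on
randomly generated layouts. Intergenic values are always recomputed from
coordinates: printed "intergenic nucleotides" columns in published
tables can carry sign inconsistencies (the bundled *C. domesticus* table
prints the 8 bp *trnW*/*trnC* overlap with a positive sign, likewise
*atp8*/*atp6* and *cytb*/*trnS2*), so that column is treated as
display-only. Two consequences worth knowing:

* Coordinate arithmetic on the bundled table yields 17 spacers and 9
  overlaps, not the 21/6 sometimes quoted for this genome; the
  difference is entirely those sign flips plus the two rRNA-involved
  overlaps.
* rRNA boundaries are annotation-soft (rRNAs lack the crisp start/stop
  signals of PCGs), so overlaps involving an rRNA (here *trnL1*/*rrnL*,
  42 bp, and *rrnL*/*trnV*, 18 bp) are tallied separately
  (`n_overlaps_rrna`) and excluded from the headline overlap extremes.
  With that convention the deepest non-rRNA overlap in the bundled table
  is *trnW*/*trnC* at 8 bp.

`classify_ends()` implements the mitochondrial stop-codon convention: a
CDS whose length leaves remainder 1 must end in `T` (reported `T--`),
remainder 2 in `TA` (`TA-`); both are flagged incomplete, reflecting
completion to TAA by polyadenylation of the transcript. Remainder 0
requires a genuine stop codon.

## Genetic code

Everything defaults to NCBI translation table 5, the invertebrate
mitochondrial code (ATA = Met, TGA = Trp, AGA/AGG = Ser, stops TAA/TAG),
taken from Biostrings; `code_id` is configurable on every
sequence-interpreting function. Published insect mitogenome statistics
essentially always presume this code even when unstated.

## Composition and skews

`AT-skew = (A − T)/(A + T)` and `GC-skew = (G − C)/(G + C)` are
dimensionless in [−1, 1]; N bases are counted but excluded from
percentages and skew denominators, and a zero denominator yields an
explicit `NA` rather than a number. The strand each class is measured on
is a real choice, because skews negate under reverse complement:

* `genome` — the J-strand as stored;
* `PCG` and the codon-position classes — each gene's coding strand
  (codon positions use complete codons only, terminal stops excluded);
* `tRNA`, `rRNA`, `control` — each feature's sense strand. For the
  rRNAs, which sit on the N strand in this architecture, this is what
  produces the familiar strongly T-rich rRNA composition (negative
  AT-skew, positive GC-skew); measuring them on the J strand would flip
  both signs.

Reported skews are rounded to 2 decimals in `characterize()` output
(the precision such statistics are conventionally printed at;
`round_digits` is configurable), while all internal values keep full
precision.

## Codon usage and RSCU

`count_codons()` counts complete codons pooled across a CDS set,
excluding stop codons and trailing incomplete (T--/TA-) stop bases, and
skipping codons containing N. RSCU scales each count so that uniform use
within a synonymous family gives 1; within every used family the values
sum to the family's degeneracy (8 for Ser under table 5, 6 for Leu, and
so on), an invariant the tests enforce on random count tables. A family
with zero occurrences has undefined (`NA`) RSCU; an unused codon in a
used family scores 0. Codons are displayed RNA-style (UUA) to match
convention, stored DNA-style internally.

One piece of arithmetic this package's recomputation settles: for the
bundled termite architecture the PCG sizes sum to 11,099 bp, yet the
commonly quoted coding total for this genome is 11,064 bp = 3 × 3,688
codons. The difference is exactly the stop codons (11 complete stops × 3
plus 2 incomplete stops × 1 = 35 bp): the 3,688-codon total is a
stops-excluded count, which is precisely what `count_codons()` computes
— the synthetic genome built on this architecture yields 3,688 counted
codons on the nose. Similarly, the tRNA sizes in the bundled table sum
to 1,462 bp although 1,459 bp is sometimes quoted; mitochar reports the
coordinate-derived value.

## Nucleotide diversity and Ka/Ks

`nucleotide_diversity()` is the mean pairwise per-site difference over
all unordered pairs with site-wise pairwise deletion: a site enters a
pair's denominator only when both sequences carry an unambiguous base
there. It needs no reading frame and is invariant to sequence order.

`nei_gojobori()` is the classic Nei–Gojobori (1986) estimator with equal
pathway weighting, chosen because it is the method the standard
population-genetics workflow (DnaSP-style) applies to mitogenome PCG
panels, and because it is exactly specifiable and therefore exactly
testable against a brute-force oracle. The concrete conventions:

* **Sites.** For each codon position, the three alternative bases are
  classified synonymous/nonsynonymous; alternatives creating stop codons
  are dropped from the denominator, so each position still contributes
  exactly one site and `N + S = 3 ×` compared codons always holds.
  Per-codon site counts are averaged between the two sequences.
* **Differences.** A codon pair differing at k positions is resolved by
  enumerating all k! orderings of single-base steps; orderings passing
  through a stop codon are excluded and the remainder weighted equally.
  In the (rare) case that every ordering passes through a stop, all
  orderings are used. Codons containing gaps or N, or that are stop
  codons, are skipped wholesale (codon-wise complete deletion) — versus
  the site-wise deletion used for π.
* **Correction.** Jukes–Cantor, `d = −¾ ln(1 − 4p/3)`, applied to pN
  and pS separately. A proportion ≥ 3/4 makes the correction undefined
  and raises an explicit saturation error rather than returning NaN.
  `ks = 0` makes ω undefined (`NA`), never infinite.
* **Panels.** Multi-taxon ω is the mean over all unordered pairs, with
  undefined-ω pairs dropped and counted.

Because the estimator family has many published variants (different
site-counting and weighting choices), recomputed Ka/Ks values for a
given accession panel are expected to land near, but not necessarily
on, previously published figures; the package's correctness claim is
oracle equivalence plus simulation recovery, not reproduction of any
specific published decimal.

## Repeat detection

`find_repeats()` reports every maximal exact repeat (extendable neither
left nor right without losing occurrences) of length ≥ `min_len`
(default 9 bp, the shortest repeat unit typically reported for termite
control regions), each once with all copy positions, via a suffix-array
scan. A hit whose occurrence set is a shifted subset of a longer hit's
is suppressed. Self-overlapping periodic repeats (homopolymer runs,
microsatellites) are collapsed to tandem arrays of one period with
fractional trailing copies truncated (`collapse_periodic = FALSE`
disables this and is the mode the brute-force oracle equivalence test
runs in). Approximate (mismatch-tolerant) repeats are out of scope.
Note that in an A+T-rich region of realistic length, exact 9-mers
recur by chance (the expected number of accidental 9 bp repeats in an
870 bp region of 67% AT is on the order of several), so a hit list
longer than the biologically salient repeats is normal, not a bug.

## Supermatrix preparation

`strip_stops()` removes the terminal stop codon column-triplet when
every non-gap sequence ends in one, and refuses alignments with internal
stops, naming the taxon and codon. `filter_columns()` is a deliberately
simple, frame-preserving stand-in for Gblocks-style ambiguous-site
removal: codon columns whose gap/ambiguity fraction exceeds
`max_gap_fraction` are dropped whole. The default is 0 (strict): with no
published parameter set to mirror, the honest default is the most
conservative one, with the threshold exposed. `concatenate_genes()`
fixes the gene order to the canonical mitochondrial PCG order (so
concatenation is invariant to input order), gap-fills missing taxon ×
gene blocks, and emits a partition table that provably tiles the matrix.
Partition schemes are written in both RAxML (`DNA, gene = start-end`)
and NEXUS `charset` dialects so ML/BI programs consume them directly.
`distance_tree()` is a neighbor-joining sanity check (p-distance or JC,
pairwise deletion, taxa pre-sorted for deterministic tie-breaks,
negative branch lengths clamped to 0) — it validates the data path, and
is not a substitute for model-based inference, which is deliberately out
of scope.

## The synthetic-data generator

`generate_mitogenome()` emulates a drywood-termite mitogenome under the
bundled 38-feature architecture: the real gene order, strands and
coordinates; target J-strand base composition A 41.8%, T 24.9%,
G 12.3%, C 21.0% (the published composition for this genome); per-PCG
start codons (ATN, GTG for *nad4*) and stop codons including the
T-- truncations of *cox2* and *nad5*; and a control region carrying an
89 bp motif duplicated at region positions 8 and 179 (copies spanning
8–267) plus a 9 bp tandem pair — the repeat structure reported for this
region. Generation is deterministic given seed + template.

Mechanically, the genome is sampled base-wise from the target
composition; PCGs are then rebuilt codon-wise: start/stop codons are
stamped first (including across gene overlaps, where the default
architecture's constraints are mutually compatible), then middle codons
are sampled with stop codons rejected. Two corrections keep the
realized composition on target: codon proposals are drawn from fractions
pre-adjusted by fixed-point iteration so that the stop-rejected marginal
equals the target, and N-strand genes are sampled from the
complement-swapped target so the J-strand (reported) composition is
preserved. Implanted repeat flanks are pinned so the motifs are exactly
maximal, making recovery checks sharp.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: codon-usage preference (synthetic codons
follow composition, so the modal codon is composition-driven rather
than UUA), tRNA secondary structure, realistic rRNA sequence, indels,
within-genome composition heterogeneity beyond the strand conventions,
and selection beyond the ω knob below.

`simulate_orthologs()` evolves each taxon independently from a root CDS
by iterated single-base proposals: proposals creating stops are
rejected outright; synonymous proposals are accepted with relative
probability 1 and nonsynonymous ones with relative probability ω (for
ω > 1 the ratio is kept by down-weighting synonymous acceptance), so
the realized per-opportunity rate ratio is exactly the target. It is a
rejection sampler, not a codon-model matrix exponential: sufficient for
estimator-recovery tests, fully specifiable, and honest about being a
star phylogeny (tree-shaped histories are composed by chaining calls,
as the test suite does for the 5-taxon supermatrix smoke test). ω = 0
is the valid pure-purifying limit; only negative ω errors. Defaults:
`subs_per_codon = 0.2` per root-to-tip path (a moderate congeneric
divergence that keeps synonymous proportions safely below Jukes–Cantor
saturation at 300-codon gene lengths) and `tstv = 1`, matching the
equal-weighting assumption of the estimator being validated; raising
`tstv` is how one would study the estimator's known transition bias.

Recovery behaviour under the defaults, recomputed by the test suite and
the acceptance script: the mean estimated ω over 20 replicate 300-codon
pairs lands within ±20% of the target at both ω = 0.1 and ω = 1.0.

## Problem sizes and numerical choices

The test suite and acceptance script run everything at desk scale:
300-codon genes and 20 replicates for recovery, repeat-oracle
equivalence on regions up to 2 kb (oracle capped at 120 bp motif
length for the largest region, comfortably above the longest implanted
89 bp motif), 100 random layouts for the conservation identity, and a
handful of full 15.7 kb genome generations (~0.1 s each). These sizes
give stable statistics while keeping the whole suite in well under a
minute of compute; scaling any of them up is a matter of changing the
obvious constants.

Tie-breaking and determinism choices: report tables are written with
fixed column order; NJ taxa are sorted before tree building; repeat
hits are ordered by decreasing motif length then first position;
`write_report()` output is byte-identical for identical input.

## Known limitations

* GenBank parsing covers the flat-file subset mitogenome records use
  (single-interval and origin-wrapping join locations, CDS/tRNA/rRNA/
  D-loop/misc_feature keys); it is not a general GenBank parser.
* Exact repeats only; the repeat module will not find the diverged
  copies of an old duplication.
* Nei–Gojobori with Jukes–Cantor is the simplest serious Ka/Ks
  estimator; for saturated or strongly ts/tv-biased data a
  maximum-likelihood estimator (outside this package's scope) is the
  right tool.
* The NJ tree is a sanity check; partition files exist precisely so a
  real inference program can take over.
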