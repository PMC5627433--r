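---
title: "Block-based characterization of protease substrate specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-based characterization of protease substrate specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockspec)
```

## The problem and the model

A protease recognises its substrates partly through the residues flanking
the peptide bond it hydrolyses. In Schechter–Berger nomenclature the four
residues N-terminal of the scissile bond are P4, P3, P2, P1 and the four
C-terminal ones are P1', P2', P3', P4'; this package works on the
corresponding 8-residue *cleavage windows*. Classical specificity summaries
(sequence logos, per-position heat maps) treat each position independently.
The point of the block representation is *subsite cooperation*: residue
preferences at adjacent positions are often coupled, and a per-position
view cannot show that, e.g., Leu at P2 is preferred specifically when Lys
occupies P1.

A *block* is a contiguous run of positions anchored at the scissile bond:
B1–B4 end at P1 (B2 spans P2–P1, B4 spans P4–P1) and the primed blocks
B1'–B4' start at P1' (B2' spans P1'–P2', and so on). Each window
contributes one k-mer ("combination") to each block it fully covers. Three
statistics are built on the block k-mer distributions of a protease's
substrate pool:

1. **Block entropy.** For each block, the plug-in Shannon entropy in bits,
   `E = -sum_i p_i log2 p_i`, of the k-mer frequencies. `E = 0` means an
   invariant combination (strict specificity, e.g. a protease that only
   accepts Asp at P1 has E1 = 0); `log2(m)` for `m` observed k-mers means
   no preference. The profile `E = (E4, E3, E2, E1, E1', E2', E3', E4')`
   is the package's fingerprint of a protease.
2. **Profile distance.** The unweighted Euclidean distance between two
   proteases' 8-entropy profiles, giving a symmetric distance matrix with
   zero diagonal over a protease collection.
3. **Prominent combinations.** A block k-mer is *prominent* when it is
   significantly enriched in the observed windows relative to simulated
   background windows drawn from the pool's own residue frequencies
   (details below).

## Redundancy filtering

Database substrate collections contain near-identical windows (the same
cleavage reported from overlapping experiments), which would inflate
counts and depress entropies. Two filters precede all statistics:

* windows with fewer than 2 non-gap residues are dropped;
* a greedy Hobohm-style filter removes windows until no retained pair has
  positional similarity >= 0.875 (7 of 8 positions equal), so every
  retained pair differs in at least two residues.

The greedy ordering is the package's choice among several consistent
readings of "starting from sequences with the maximum number of similar
amino acids": we build the conflict graph at the threshold and repeatedly
delete the window with the highest current conflict degree, recomputing
degrees after each deletion and breaking ties toward the later input
window. This maximises the retained set greedily and is deterministic;
other orderings can retain different (equally valid) sets of the same
irredundancy guarantee. Similarity is strictly positional — windows are
already anchored at the bond, so no alignment is involved — and gap–gap
positions do not count as matches, so two terminus-truncated windows are
not called similar merely for sharing missing data. The pair scan is
O(n^2), fine for database-scale pools (n up to ~10^4 per protease).

## Gaps and truncated windows

Windows whose parent protein ends inside the window are padded with `-` at
the affected terminus (only there; interior gaps are rejected as input
corruption). When a gap falls inside a block's span, the window is skipped
*for that block only* — it still contributes to blocks it fully covers, and
block frequencies divide by the block's own contributing count. Whether
the original analysis dropped such windows globally or per block is not
documented; per-block exclusion retains the most data. A consequence worth
knowing: entropy monotonicity under refinement (E1 <= E2 <= E3 <= E4, and
likewise for primes), which is guaranteed on gap-free data because a k-mer
distribution refines its (k-1)-mer distribution, can fail when gap
exclusion changes the contributing subset between blocks; the test suite
asserts it on gap-free sets only.

## The prominence test

For one block of one protease with `n` (filtered) windows:

1. `N` = number of distinct k-mers observed in the block; the Bonferroni
   threshold is `alpha / N` with `alpha = 0.05` by default. `N` is scoped
   to the block of the protease under test — the most local reading of
   "number of different kinds of combinations".
2. Each of `reps = 1000` repetitions draws a background set of `n`
   gap-free windows with every position sampled independently from the
   pool's empirical residue frequencies (per-position by default; a pooled
   single-frequency mode is available). Equal experiment/background sizes
   keep the two margins of the contingency table comparable.
3. For each observed combination, the 2x2 table counts windows containing
   vs not containing it ("containing" = the window's block k-mer equals it
   exactly) in experiment vs background, and the one-sided Fisher exact
   test gives the enrichment p-value: the sum of hypergeometric point
   probabilities `(a+b)!(c+d)!(a+c)!(b+d)!/(a!b!c!d!n!)` over tables at
   least as enriched, computed in log space. One-sided because the
   question is over-representation; a two-sided test would also flag
   depletion, which is not part of the analysis.
4. A combination earns a vote when `p < alpha / N`; it is prominent when
   it collects votes in *more than half* of the repetitions (at even
   `reps`, exactly half is not enough). The median p-value across
   repetitions is reported for ranking but never used for calling.

Windows with a gap inside the span count on the "not containing" side, so
the table margins stay at `n`. Note that a block can only be empty of
contributors when an entire flank position has no data (gaps are terminal
runs), in which case the per-position background is undefined too; such
blocks are skipped with a warning and the pooled background is the way to
analyse the remaining blocks.

Because the p-value at fixed margins depends only on the pair (observed
count `a`, background count `c`), the implementation precomputes the
p-value vector over all `c` for each distinct `a` and, per repetition,
only samples the block's span positions and tabulates background counts —
algebraically identical to testing every table, but fast enough for
1000 x 8 repetitions in seconds. Repetition `r` of block `b` runs under
seed `(seed + 104729 (b-1) + 7919 r) mod (2^31 - 1)`, so results are
reproducible and independent of evaluation order.

Summaries mirror the two standard displays: per-protease *coverage* (the
fraction of windows matching any prominent combination per block, binned
into five 20%-wide shades with a separate "none" state when a block has no
prominent combination) and cross-protease *proportions* (percentage of
proteases with at least one prominent combination per block).

## PCA of entropy profiles

`pca_correlation()` eigendecomposes the 8x8 Pearson correlation matrix of
the block entropies across proteases (the "correlation method": every
block enters on equal footing). Components with eigenvalue > 1 are
retained (Kaiser criterion); variance explained is eigenvalue/8 x 100
since the correlation-matrix trace is 8. Loadings are eigenvectors scaled
by sqrt(eigenvalue), i.e. block–component correlations, and each
component's sign is fixed so its largest-magnitude loading is positive
(eigenvectors are sign-ambiguous; the convention makes output
deterministic). Rotation (varimax) and sampling-adequacy statistics are
deliberately not included: they calibrate the presentation of loadings,
not the method, so loadings here are the unrotated ones and will differ
in detail from rotated reports. Fewer than ~9 proteases triggers a
warning — an 8-variable correlation matrix estimated from fewer rows is
rank-deficient or unstable.

## The synthetic generator

`generate_substrate_set()` emulates a database-style window collection
with controlled structure; it is first-class, tested code, not a fixture
dump. In order: draw `n` gap-free windows from the background (uniform by
default, or any estimated background model); overwrite each planted
block's span with its k-mer in a uniformly chosen carrier subset of
exactly `round(n * fraction)` windows — plants overwrite *after* sampling,
so the carrier fraction is exact rather than in expectation and power
analyses are deterministic in the effect size; append near-duplicates
(copies mutated at exactly one position) to exercise the redundancy
filter; truncate a random subset by replacing a 1–3 position terminal run
with gaps, mirroring the terminus convention. Everything is
bit-reproducible from the spec's seed.

What it does **not** emulate: real proteome residue composition,
correlated positions beyond the planted motifs, protease families sharing
substrates, or cleavage kinetics. Passing tests therefore demonstrate the
machinery's correctness and statistical calibration under known
conditions, not biological conclusions about any real protease.

`caspase3_fixture()` is the running example: 300 windows, uniform
background, the canonical caspase-3 motif DEVD planted across P4–P1 in
60% of windows, fixed seed. `find_prominent()` on it recovers the nested
combinations VD at B2, EVD at B3 and DEVD at B4 — and *not* D at B1,
because the per-position background absorbs single-position composition:
prominence specifically captures multi-position cooperation beyond
position-wise frequencies.

```{r fixture}
fx <- caspase3_fixture()
entropy_profile(fx)
rec <- find_prominent(fx, reps = 300, seed = 19)
rec[rec$prominent, c("block", "kmer", "count", "votes", "median_p")]
```

## Numerical choices and problem sizes

* Entropies are plug-in estimates in bits; no small-sample correction
  (Miller–Madow etc.) is applied, matching the method's definition.
  `0 log 0` is 0, and the one-component case is clamped to exactly +0.
* Fisher tails are summed in log space with a max shift; against exhaustive
  enumeration over all margins with table total <= 60 the implementation
  agrees to better than 1e-12.
* Distances are full double precision internally; writers round to 3
  decimals, the precision at which such matrices are usually reported.
* Default test and demonstration sizes — sets of 100–300 windows, 1000
  Fisher repetitions, 20-seed null calibrations — were chosen as the
  smallest sizes at which the planted-motif power analysis is stable
  across seeds; the full suite runs in a couple of minutes on one core.

## Known limitations

* The prominence background is estimated from the same windows being
  tested; with very few windows the background is noisy and the test
  conservative (a set of identical windows can never be enriched against
  its own point-mass background — by design).
* Per-block Bonferroni scoping (`N` = combinations in that block) is one
  of several defensible multiplicity scopes; a global scope would be more
  conservative.
* The greedy filter guarantees irredundancy, not maximum retained size
  (maximum independent set is NP-hard); different orderings give slightly
  different retained sets.
* Entropy profiles depend on pool size: two proteases with identical
  specificity but very different substrate counts have different k-mer
  saturation, hence different entropies. Distances between proteases with
  very unequal pools partly reflect sampling depth.
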