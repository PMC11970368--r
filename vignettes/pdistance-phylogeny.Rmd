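---
title: "Streaming p-distances and distance-based phylogenies from VCF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming p-distances and distance-based phylogenies from VCF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcfpdist)
```

## The model

`vcfpdist` estimates genetic distance between individuals as the
p-distance: the proportion of compared sites at which their genotypes
differ. For individuals $i$ and $j$,

$$D_{ij} = \frac{\sum_{l=1}^{L_{ij}} d_l}{L_{ij}},$$

where the sum runs over the $L_{ij}$ sites at which *both* individuals
carry a called genotype. The per-site score $d_l$ compares genotype calls
as tuples of allele indices, never as sequence: REF is allele 0, ALT
alleles are 1, 2, ... in order. Because only indices are compared, SNPs,
indels and multiallelic records are handled identically and no site
filtering is performed — the estimate is deliberately a function of the
input genotypes as given.

Two rules produce $d_l$:

* **Unordered (either call unphased).** With ploidy $p$,
  $d_l = 1 - |a \cap b|_{\text{multiset}} / p$. For diploids this yields
  the familiar values: identical genotypes 0, hom–het 0.5, opposite
  homozygotes 1. A shared allele in a multiallelic het pair (e.g. 1/2 vs
  0/2) scores 0.5.
* **Positional (both calls phased, equal ploidy).** The haplotypes are
  aligned: $d_l$ = fraction of positions with differing allele index, so
  `1|0` vs `0|1` scores 1 while the same unphased genotypes score 0.

Assumptions worth stating: the p-distance is an identity-by-state
proportion, not a model-corrected divergence (no Jukes–Cantor correction,
no allele-frequency weighting); phase is trusted wherever both calls carry
it; and genotype quality is ignored.

## Missing data and edge cases

* A call containing any missing component (`.`, `./1`, `0/.`) is dropped
  whole. The unordered alternative — scoring the called half — would make
  the score depend on which half is missing and break the symmetry of the
  multiset rule, so whole-call exclusion is used.
* Denominators are per-pair (`pairwise deletion`): $L_{ij}$ counts only
  sites where both members are called. This keeps $0 \le D_{ij} \le 1$
  under any missingness pattern. A pair with no shared called site is
  *undefined*: written as the sentinel `-1` in the Phylip matrix and fatal
  if a tree is requested, since silently imputing a distance would produce
  a nonsense topology.
* A pair whose two calls have different ploidy at a site skips that site;
  the skip count is reported in the run log. For equal ploidies above 2
  the two scoring rules generalize unchanged (supported up to ploidy 8).

## Streaming and determinism

Input is read line by line in chunks of `chunk_sites` records (default
10,000), so resident state is $O(\text{chunk} \times n)$ regardless of the
number of variants. Only the upper triangle of pair sums is accumulated.
Per-site scores for ploidy $\le 2$ are exact binary fractions, so the
double-precision per-pair sums are exact and accumulators built from
disjoint site blocks merge exactly.

The `workers` argument partitions sample pairs into contiguous blocks and
accumulates each block independently; every pair belongs to exactly one
block and its sites are visited in stream order, so output is bit-identical
for any worker count. This makes the parallel decomposition testable as a
contract rather than a property of scheduler timing.

The distance stage performs $n(n-1)/2$ comparisons per variant,
$\Theta(n^2 m)$ overall; NJ adds $O(n^3)$. For typical inputs
($m \gg n$) the distance stage dominates.

## Alignment input

Aligned FASTA and Phylip ("phy") files are exposed to the same engine by
treating each column as a haploid site: the distinct non-ambiguous
characters observed in a column define its allele set. Gaps and unknowns
(`-`, `.`, `N`, `?`, `X`) and all IUPAC partial ambiguities (R, Y, S, W,
K, M, B, D, H, V) count as missing; a partially ambiguous base constrains
but does not determine the state, and the p-distance is defined only over
characters that can actually be compared. Phylip parsing is relaxed
(names are the first whitespace token, no 10-character truncation) because
modern files routinely violate strict Phylip; both sequential and
interleaved layouts are detected by attempting sequential reassembly first
and falling back to cyclic block assembly.

## Trees

NJ follows Saitou–Nei with the Studier–Keppler criterion
$Q(i,j) = (r-2)D(i,j) - R_i - R_j$ and the standard branch-length
formulas, ending in an unrooted trifurcation. Negative branch lengths are
retained as computed — they are information about non-additivity — with an
optional `clamp_negative` switch for tools that reject them. UPGMA uses
cluster-size-weighted average linkage with node heights $D/2$, so its
trees are rooted and ultrametric. Both methods break ties in the selection
criterion by the lexicographically smallest active index pair, which makes
output independent of platform-specific floating-point ordering quirks.
Both are implemented natively against the `phylo` structure, so results
interoperate with the wider R phylogenetics ecosystem and can be
cross-checked against independent implementations (the test suite does
exactly that, against `ape::nj` and average-linkage `hclust`).

## Bootstrap and consensus

The site-resampling bootstrap draws `round(ratio * m)` site indices with
replacement per replicate (default ratio 0.25, minimum one draw,
round-half-even), keeps duplicate draws with multiplicity, rebuilds the
distance matrix restricted to the drawn multiset (pairwise-deletion
denominators apply within the draw), and rebuilds the tree. Replicate
trees are written one per line so external consensus programs can also
consume them.

Consensus is strict-majority: a non-trivial bipartition is retained iff
its frequency strictly exceeds the threshold (default 0.5). Strict
majority guarantees the retained splits are pairwise compatible, so the
consensus tree always exists and the construction is deterministic; this
is simpler than extended majority-rule consensus, which greedily adds
sub-majority splits and can be order-dependent. Supports are
`round(100 * frequency)`; consensus branches carry supports only, no
lengths, because averaging lengths across replicates with different
denominators has no clean interpretation.

All resampling uses one seeded RNG stream; the seed is echoed in the run
log so any published tree can be regenerated exactly.

## The synthetic-data generator

`simulate_vcf` plants group structure with a two-frequency scheme chosen
for analytic tractability rather than realism: per site each group has a
base allele (group 1 always 0; other groups switch to allele 1 with
probability `between_diff_prob`), and each sample is independently
heterozygous for a site-level deviant allele with probability
`within_diff_prob`. Multiallelic sites (fraction `multiallelic_fraction`)
use a third allele as the deviant. This gives closed-form expected
distances — within groups $w(1-w)$; between groups, conditional on
differing bases, $1-w$ at biallelic and $1-w^2/2$ at triallelic sites —
which the generator writes alongside the VCF, so convergence of the
estimator is testable against an analytic target instead of a second
simulation.

Defaults (two groups of five, 1,000 sites, $w = 0.05$, between 0.3,
20% phased, 5% missing, 5% multiallelic) describe a modest
two-population resequencing panel with clear but not degenerate
structure. What the generator does **not** emulate: linkage
disequilibrium (sites are independent), realistic allele-frequency
spectra, coalescent genealogies within groups, genotyping-error
structure correlated with depth. Tests passing on these fixtures
demonstrate the engine computes the defined statistic correctly, not that
the statistic resolves any particular real population history.

`simulate_alignment` evolves a root sequence down a given tree under a
symmetric 4-state process (substitution probability
$\frac{3}{4}(1 - e^{-4\,\text{rate}\,t/3})$ per branch), so expected
p-distances increase monotonically with path length — sufficient for
topology-recovery tests on the alignment path.

## Numerical and design choices

* Matrix output is fixed-point with 6 decimals by default; the Phylip
  reader accepts square and lower-triangle layouts and rejects asymmetry
  beyond the printed precision (half a unit in the last printed decimal).
* Bootstrap replicates are computed from cached parsed chunks (compact
  integer arrays, about $4 p\, n$ bytes per site) rather than by
  re-streaming the input once per replicate; at the scales this package
  targets the cache is far cheaper than $B$ extra passes over the file.
  Exceedingly large inputs can be bootstrapped externally from the
  replicate-tree file interface instead.
* Gzip input is detected from magic bytes, not the file extension; bgzip
  is gzip-compatible and handled identically.
* Test problem sizes — 200 random fixtures up to 20 samples × 500 sites
  for the oracle-equivalence suite, 100 random trees of 5–20 taxa for NJ
  and UPGMA consistency, one 50-sample × 100,000-site fixture for the
  worker-determinism check — were chosen so the full suite exercises
  multi-chunk streaming and non-trivial tree sizes while remaining quick
  to run routinely.

## Known limitations

* Only the GT field is read; depth/likelihood-aware distances are out of
  scope, as are model-corrected distances (Jukes–Cantor and relatives)
  and IBS variants.
* Phase is compared only when both calls are phased; a dataset with
  inconsistent phasing conventions will silently fall back to the
  unordered rule for mixed pairs.
* Consensus is strict-majority, not the extended majority rule of
  Phylip-family `consense`; supports below 50% are never shown.
* The bootstrap resamples sites independently, which understates
  uncertainty in the presence of strong linkage disequilibrium.
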