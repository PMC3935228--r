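---
title: "Barcode-gap species delimitation with barcodegap: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-gap species delimitation with barcodegap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

This vignette documents the models behind `barcodegap`, the parameters
that matter, the numerical choices, and what the built-in simulator does
and does not emulate. The workflow it implements is the one used to pull
cryptic species apart with COI barcodes: corrected pairwise distances, a
distance tree, the within/between divergence "gap", fixed diagnostic
characters, and short mini-barcode "ID tags" for degraded museum DNA,
with a small morphometric discriminant on the side.

## Distances

All distance work starts from `pairwise_counts()`, which compares two
aligned sequences column by column under **pairwise deletion**: any
column holding a gap or an IUPAC ambiguity code in *either* sequence is
excluded before counting. This is the conservative convention for
mixed-quality data — an `N` never counts as either a match or a
mismatch. Transitions are A↔G and C↔T; every other differing pair of
unambiguous bases is a transversion.

The Kimura 2-parameter distance corrects the observed transition and
transversion proportions \(P\) and \(Q\) for multiple hits:

\[ d = -\tfrac{1}{2}\,\ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right] \]

in substitutions per site. Two properties are load-bearing and tested:
\(d \ge p\) always (the correction never shrinks the observed distance,
with equality only at \(p = 0\)), and \(d \approx p\) for small
distances. Note the agreement is not unlimited: at exactly \(p = 0.01\)
composed purely of transitions the correction is \(1.01\times10^{-4}\),
so "agreement within \(10^{-4}\)" holds strictly below that corner or
with mixed substitution types.

**Saturation** (\(1-2P-Q \le 0\) or \(1-2Q \le 0\)) is an error, not a
missing value: `k2p()` and any K2P-metric matrix construction fail
loudly, naming the offending pair, so garbage input cannot flow silently
downstream. The uncorrected proportion metric (`metric = "p"`) remains
available and never saturates; `pairwise_counts()` itself therefore
records `d_k2p = NA` for a saturated pair instead of refusing to count.

Percent values are reported rounded **half away from zero** to one
decimal (`percent_1dp()`), the style distances are conventionally quoted
in (3.4%, not 3.45); raw values are always retrievable.

## Group divergence and the barcode gap

`group_divergence()` summarizes a distance matrix per species: mean,
sample standard deviation (\(n-1\) denominator) and maximum over
unordered within-group pairs, and min/mean/max over cross-group pairs.
Singleton groups report *absent* (`NA`) within-group statistics rather
than zero — a deliberate distinction, because a divergence average over
real pairs is not the same claim as "no variation observed".

`barcode_gap()` then asks, per group pair, whether
\(\max(\text{within}) < t \le \min(\text{between})\) at a threshold
\(t\) (default 2, in percent). The default reflects the empirical
observation in this genus of a clear hiatus around 2% between
intraspecific and interspecific distances. `delimit_clusters()`
operationalizes the threshold as single-linkage components joining pairs
**strictly below** \(t\); the strict comparison makes a borderline pair
at exactly 2.0% split, consistent with treating "at least 2% different"
as between-species evidence. Cluster numbering is deterministic (by the
alphabetically smallest contained label).

## BioNJ and the bootstrap

`bionj_tree()` implements neighbor joining with the BioNJ
variance-weighted reduction: pairs are chosen by the usual Q criterion,
branch lengths come from the standard split formulas, and when nodes
\(i, j\) merge into \(u\), the new distances are
\(d_{uk} = \lambda (d_{ik} - b_i) + (1-\lambda)(d_{jk} - b_j)\) with
\(\lambda\) chosen to minimize the variance of the reduced distances
(clamped to \([0,1]\); \(\lambda = \tfrac12\) recovers classical NJ and
is used when the pair variance is zero). On additive matrices the
generating topology is recovered and all path lengths reproduce the
input to \(10^{-9}\) — a property the tests enforce up to 8 taxa against
brute-force oracles.

Numerical choices:

* **Tie-breaking.** When several pairs tie on the Q criterion (within a
  relative \(10^{-12}\)), the pair whose contained leaf labels sort
  first lexicographically wins. The output is a deterministic function
  of the matrix.
* **Negative branch lengths** are kept as computed and flagged with a
  message, never clamped — clamping would destroy the additivity
  invariant and silently change path lengths.
* **Rooting.** Trees are built and emitted unrooted; display rooting by
  outgroup is an option of `write_newick()` only.

`bootstrap_tree()` resamples alignment columns with replacement,
rebuilds matrix and tree per replicate, and streams canonical
bipartition counts (no replicate trees are retained). A split is keyed
by the side *not* containing the alphabetically smallest leaf, making
supports invariant to leaf order. Supports are percentages of successful
replicates; replicates whose resampled distances saturate are skipped
and counted in `attr(tree, "n_skipped")`. The default of 100 replicates
is the conventional minimum for quoting percent supports; a seed is
required, and the same seed reproduces the supports exactly.

## Diagnostic sites, ID tags and virtual PCR

`find_diagnostic_sites()` emits the columns at which every species
sample is invariant **and unambiguous** — a single `N` in one member
disqualifies a column, because "invariant" must be demonstrable, not
assumed. With more than two species a column qualifies as soon as any
pair differs, and all species states are recorded.

`select_tag_windows()` ranks fixed-length windows by the lexicographic
score `(pair_min, site_count)`: first maximize the *weakest* pairwise
discrimination inside the window, then the total number of sites. The
per-pair-first objective is the right one for an identification assay —
a window with many sites that all separate the same single pair still
cannot tell the other pairs apart. Ties prefer the leftmost start, and
windows containing identical site sets collapse to the leftmost, so the
ranking is stable under permutation of the site list.

Primer matching is IUPAC **set intersection** at every position
(a degenerate `W` matches A or T; `N` matches anything; a gap matches
nothing), with zero mismatch tolerance — thermodynamics, near-matches
and dimers are out of scope. Forward primers bind the plus strand as
written; reverse primers bind via their reverse complement. All
coordinates are 1-based closed intervals on the plus strand.
`virtual_pcr()` requires each primer to bind exactly once and in the
correct order; multiple binding sites abort the amplification (the
in-silico analogue of non-specific PCR), as does a reverse site upstream
of the forward site.

`call_species()` scores a fragment at every diagnostic site it covers:

* all scorable sites compatible with exactly one species → that label;
* compatible with several (possible when species share states at the
  covered sites) → `ambiguous`;
* sites backing *different* species, or ambiguity codes at diagnostic
  sites → `contaminated` (the signature of mixed templates);
* no scorable site, or a single site matching nothing (e.g. a private
  mutation) → `no-match`.

One subtlety worth knowing: whether a chimeric fragment is flagged as
contaminated depends on the profile it is scored against. A half-and-half
splice of two species' tag inserts conflicts under the two-species
profile, but can be perfectly consistent with a *third* species whose
states happen to coincide with each half — the verdict rules then
correctly name that species. Contamination detection is only as good as
the reference panel.

## Morphometrics

`morpho_score()` maps the six genitalic lengths onto
\(u = a/b + w\,c/d\) (uncus shape; \(w = 0.5\) by default, down-weighting
the length ratio that discriminates less well) and \(v = h/l\) (valva
base shape). Both are ratios, hence dimensionless and scale-invariant;
only within-specimen unit consistency matters. The weight is exposed as
a parameter but fixed at 0.5 by default.

`separability()` deliberately reports *linear separability with a
witness boundary* rather than fitting a classifier: the scientific claim
being checked is "the plot separates the two species", and a fitted
classifier (LDA, PCA rotations) would change with the data at hand.
Strict separability is decided exactly by searching a finite candidate
set of projection directions — normals to lines through every point pair
(each also rotated by \(\pm10^{-7}\) radians), cross-class difference
vectors, and the axes — which covers every vertex–vertex and
vertex–edge closest-pair configuration of the two convex hulls. If no
direction strictly separates, the minimum misclassification count over
all lines is found by optimal 1-D thresholding along the same
directions; the tiny rotations matter because an optimal boundary
through two tied points may need those points on opposite sides. The
test suite checks this against an independent enumeration of lines
through point pairs on up to 20 points.

## The simulator: what it emulates, and what it does not

`simulation_config()` defaults encode the study design the pipeline
assumes:

| parameter | default | rationale |
|---|---|---|
| `n_species` | 3 | three sympatric/parapatric congeners |
| `target_divergence` | 2%, 3.4%, 4.5% (K2P) | the observed span of between-species distances |
| `intra_max_diffs` | 3 | haplotypes differ by 1–3 substitutions, keeping within-species divergence below 1% |
| `kappa` | 4 | transition/transversion rate ratio typical of insect mtDNA |
| `base_composition` | A .31, C .15, G .15, T .39 | AT-rich COI |
| `seq_length` | 658 | the standard COI barcode |
| `n_per_species` | 20 | a realistic per-species sample |

`simulate_species_set()` draws an ancestor, solves per-species
substitution counts from the target grid (least squares on the star
decomposition \(m_i + m_j = n_{ij}\), where \(n_{ij}\) inverts the
expected-K2P curve at the configured \(\kappa\)), and places
between-species substitutions at globally **distinct** positions
(infinite-sites style). That guarantees fixed differences exist by
construction; within-species mutations may hit any position, which
realistically erodes some of them — mirroring real data, where pairwise
differences outnumber strictly diagnostic positions. Triangle-violating
grids and grids without a non-negative star decomposition are rejected
up front; realized consensus K2P is recomputed with the distances module
and must land within ±10% of each non-zero target, or the configuration
errors out as unattainable. Everything is reproducible byte-for-byte
from the seed.

`degrade_fragments()` models old-specimen DNA purely as fragmentation:
contiguous non-overlapping pieces with Poisson lengths around the
requested mean, floored at `min_len`, carrying their true alignment
offsets (so reassembly is exact). `simulate_morphometrics()` draws
independent Gaussian noise around two group mean vectors, truncated at a
small positive floor.

What the simulator does **not** emulate — and hence what green tests do
not certify about real data: coalescent genealogies and incomplete
lineage sorting, indels and alignment error, heterogeneous rates across
sites or lineages, sequencing error and chromatogram noise, and real
contamination (tests construct chimeras explicitly instead). Passing the
end-to-end recovery test shows the pipeline is internally consistent
under its own model, not that 2% is the right threshold for any
particular taxon.

## Problem sizes and runtime

The test suite runs in well under a minute on one core: brute-force
oracles cap at 8 taxa (tree additivity), 15 topologies (5-taxon
exhaustive search), 20 points (separability), 20 × 700 columns
(diagnostic-site scans); the bootstrap uses 50–100 replicates on 4–60
sequences; the simulator's ±10% divergence calibration is checked across
50 seeds at one haplotype per species. These sizes were chosen as the
smallest at which the properties are non-trivial; all scale linearly or
quadratically if enlarged.

## Known limitations

* Only the K2P and p distances are provided; no JC/TN93/GTR, no
  maximum-likelihood branch lengths, no rate heterogeneity.
* Primer matching is exact (set intersection); a single real mismatch
  that a polymerase would tolerate makes a binding site invisible.
* `separability()` is 2-D by design (the two discriminant coordinates);
  it is not a general linear classifier.
* The metadata model stores dates and curatorial annotations as free
  text and does not interpret them.
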