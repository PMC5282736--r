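---
title: "Quantifying morphospace occupation from discrete character matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying morphospace occupation from discrete character matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lobomorph)
```

## The problem

Palaeontologists routinely ask whether named clades occupy distinct regions
of morphospace, and how much of it each clade explores. For soft-bodied
Palaeozoic panarthropods ("lobopodians") — and for most fossil groups — the
raw data are not landmark coordinates but a cladistic matrix: taxa scored
for a few dozen discrete characters, with many cells missing (`?`),
logically inapplicable (`-`), or polymorphic (`{01}`). `lobomorph`
implements the complete analysis chain for that situation:

1. pairwise taxon dissimilarities under pairwise deletion
   (`pairwise_dissimilarity()`);
2. principal coordinates analysis with Broken-Stick axis selection
   (`pcoa_ordination()`);
3. group disparity as jackknifed sums of ranges with permutation tests
   (`jackknife_disparity()`, `permutation_test()`);
4. kernel-density hypervolumes per group, Sorensen-Dice overlap, point
   inclusion tests and centroid distances (`estimate_hypervolume()` and
   relatives);
5. a neighbour-joining phenogram and a k-means cluster-number assessment
   (`neighbour_joining()`, `kmeans_assessment()`);
6. a one-call orchestration with a reproducible results bundle
   (`run_pipeline()`).

A synthetic-data module (`generate_matrix()`, `generate_point_clouds()`)
plants known group structure so every stage can be validated without any
fossil dataset.

## Dissimilarities for incomplete discrete data

For a taxon pair, only characters scored in *both* taxa are compared
(pairwise deletion). Inapplicable cells are treated exactly like missing
ones: an inapplicable score carries no usable difference information for a
distance, even though the data model keeps the two tokens distinct so
alternative treatments remain testable.

With per-character difference $d_j$ (0/1 mismatch for unordered characters,
$|a-b|$ for ordered ones) and maximum attainable difference $m_j$ (1 for
unordered, the observed state range for ordered), the three indices over
the comparable set $C$ are

* Gower: $\frac{1}{|C|}\sum_{j \in C} d_j / m_j$,
* MORD (maximum observable rescaled distance):
  $\sum_{j \in C} d_j \big/ \sum_{j \in C} m_j$,
* Hamming: the raw mismatch proportion, ignoring ordering.

On fully unordered matrices all $m_j = 1$ and the three coincide; the
default is MORD, the standard choice for cladistic matrices with abundant
missing data. Polymorphic cells are resolved by the minimum difference
across the two state sets (configurable to the mean). Two caveats are
deliberate: distances built on per-pair character subsets need not satisfy
the triangle inequality (documented, not "fixed"), and a pair with zero
comparable characters yields an undefined distance that makes downstream
ordination *fail fast* rather than silently impute — the cure is removing
missing-data-rich taxa (`filter_outliers()`), whose few scored cells
otherwise make them spurious ordination outliers.

## Ordination and axis selection

`pcoa_ordination()` double-centres $-\tfrac12 D^2$ and eigendecomposes it
(delegating to `ape::pcoa`). Gower-type distances are generally
non-Euclidean, so negative eigenvalues appear; the default drops them with
a warning, and the Lingoes and Cailliez additive corrections are available
because a correction changes both coordinates and the retained-axis count.
Eigenvector signs are arbitrary, so each axis is anchored with its
largest-magnitude loading positive, making output files stable across
platforms.

The number of "significant" axes follows the Broken-Stick model: with $p$
positive eigenvalues the null expectation for axis $k$ is
$b_k = \frac1p \sum_{i=k}^{p} 1/i$, and leading axes are retained while
their relative eigenvalue (as a proportion of the summed *positive*
eigenvalues) exceeds $b_k$, stopping at the first failure, floor one. The
first-failure rule is the conservative standard; an axis that beats the
null after one that does not is noise by this criterion.

## Disparity statistics

The sum of ranges (per-axis max minus min, summed over the retained axes)
measures the extent of morphospace a group spans; the sum of variances is
its dispersion-based, size-insensitive companion. Ranges grow with sample
size, so groups of different sizes are compared after rarefaction:
`jackknife_disparity()` resamples each group without replacement at a
common subsample size — by default the smallest group-of-interest size —
for the requested number of iterations (default 5000). At that default the
smallest group's replicates equal its observed value; the distributions are
what violin plots of jackknifed disparity show, and the jackknife mean is
always at or below the observed range (a bias the tests assert).

Group differences are tested by permutation: pool the two groups' taxa,
re-partition at random into the original sizes, and take
$p = (\#\{|\Delta_{\text{null}}| \ge |\Delta_{\text{obs}}|\} + 1)/(B + 1)$,
which is never exactly zero. The implementation canonicalises the pooled
row order and always draws the smaller subset, so $p$ is exactly invariant
under swapping which group is called A and which B. Calibration is tested,
not assumed: under the null the rejection rate at $\alpha = 0.05$ stays
within [0.03, 0.07] over 1000 simulations, and a 3-fold spread ratio at 15
taxa per group is detected in at least 95% of runs.

## Kernel-density hypervolumes

A group's occupied region is modelled as the set where a Gaussian
product-kernel density estimate of its coordinates exceeds a threshold.
Bandwidths default to Silverman's multivariate rule per axis,
$h_j = \sigma_j \left(\frac{4}{(d+2)n}\right)^{1/(d+4)}$, and are
configurable because Silverman over-smooths strongly clustered data. The
threshold is the `threshold_quantile` (default 0.05) quantile of the
density evaluated at draws from the kernel mixture itself, so the retained
region holds 95% of the mixture's probability mass.

The region's volume is estimated by importance sampling rather than grid
integration, which would not scale to four dimensions: with $X \sim f$,
$\mathrm{Vol}\{f \ge t\} = E_f[\mathbf 1\{f(X) \ge t\}/f(X)]$, averaged
over the same mixture draws. Retained draws resampled with weights $1/f$
give uniformly distributed interior points; by construction they pass the
model's own inclusion test, and volume = point count / point density is an
exact identity of the estimator. Sorensen-Dice overlap
$2V(A \cap B)/(V(A)+V(B))$ uses cross-inclusion of each model's uniform
points in the other model, averaging the two intersection estimates. A
query taxon is "inside" a hypervolume when the fitted density at its
coordinates reaches the threshold.

Monte-Carlo tolerances are stated explicitly in the tests: volumes within
15% of closed-form oracles (unit square, Gaussian contour) at the default
sample sizes, Sorensen within 0.05 of its 0/1 limits for disjoint/identical
clouds. Groups smaller than 3 points (up to two dimensions) or $d+1$ points
(above) are reported and skipped — a KDE on fewer points than dimensions
has degenerate support. Centroids default to data-point means; means of the
hypervolume's uniform interior points are available behind a flag, since
the two disagree for skewed clouds.

## Clustering views

`deduplicate()` merges taxa within a distance tolerance (default: exact
duplicates), averaging their distances, because identically coded taxa add
zero-length cherries to trees. `neighbour_joining()` delegates to
`ape::nj`; non-additive input can produce negative branch estimates, which
are clamped to zero with the deficit transferred to the adjacent branch (a
standard Kuhner–Felsenstein-style repair that preserves path lengths
through the node), and the number of clamped branches is recorded.

No agreed test decides "how many k-means groups are significant", so
`kmeans_assessment()` operationalises it as the silhouette-optimal $k$
(best of 25 restarts per $k$), with the gap statistic (first-SE-max rule)
as an alternative. A best silhouette below 0.4 is flagged as weak evidence
of any structure — a single 4-dimensional Gaussian blob scores around
0.2–0.3, well under that line, while planted well-separated blobs exceed
0.7.

## What the synthetic data emulate — and what they do not

`generate_matrix()` plants: group-specific modal states on a chosen
fraction of characters (with the group-to-state mapping randomised per
character so no two groups coincide when states are scarce), per-group
noise around the modal profile, missing cells at a flat rate, inapplicable
cells as one contiguous character block per taxon (anatomical
inapplicability hits neighbouring characters, such as every limb character
of a limbless taxon), and optional missing-data-rich outlier taxa. It does
**not** model character correlation or phylogenetic autocorrelation:
characters are independent draws, so synthetic eigenvalue spectra are
flatter than those of real matrices, where correlated character suites
concentrate variance on leading axes. Passing tests therefore demonstrate
that the statistics recover *planted* structure at realistic noise levels,
not that any particular fossil dataset has such structure.

The `study-shape` preset (`synthetic_study_matrix()`) emulates the
conditions of the motivating 19-taxon, 39-character lobopodian analysis,
whose original matrix ships with the source publication's supplementary
files and is not redistributable here. Choices, fixed once: 30 binary plus
9 three-state characters; groups H (6 taxa), L (5) and O (5); twelve
characters separate O from a shared H+L state and eight separate H from L,
so H and L are mutually closer than either is to O; per-group noise 0.35
(H), 0.28 (L) and 0.15 (O) makes H the widest cloud and O the most
conservative; 15% missing and a 5% inapplicable block match typical
fossil-matrix incompleteness; three ungrouped query taxa are drawn from the
H, H and L profiles respectively to play the morphologically intermediate
fossils used in inclusion tests. With only 19 taxa the qualitative
recoveries (volume ordering, tree grouping, inclusions) hold at the
documented seeds but do vary across seeds — small samples at these noise
levels genuinely carry that much uncertainty, which is worth remembering
when reading the equivalent analyses of real 19-taxon datasets.

## Numerical conventions

* One master seed per run; each pipeline stage derives a fixed child seed
  (`seed * 101 + stage * 7919 mod 2^31 - 1`), so stages can be re-run in
  isolation and a rerun is bit-identical.
* Tabular outputs are CSV at six significant digits with fixed column
  order; trees are Newick; the manifest (JSON) embeds the resolved
  configuration verbatim.
* Degenerate inputs are defined, not crashed on: an all-zero distance
  matrix ordinates to a single zero axis; a single point has zero range; a
  zero-variance axis requires an explicit bandwidth.
* Test problem sizes are chosen to make stochastic checks sharp but quick:
  1000 null simulations for type-I calibration, 200 repeats for power, 100
  seeds for centroid recovery, $10^5$ kernel-mixture samples for volume
  oracles.

## Known limitations

* MORD/Gower under pairwise deletion is not metric; the neighbour-joining
  view is a phenogram of dissimilarities, not an additive-tree estimate.
* Hypervolumes inherit KDE pathologies: Silverman bandwidths over-smooth
  multimodal groups, and volumes in more than ~6 dimensions would need far
  larger sample counts than the defaults.
* Character ordering support is per-character binary (ordered/unordered);
  step matrices and character weights are out of scope.
* The generator's independence assumption understates leading-axis
  dominance relative to real matrices (see above), which also makes
  Broken-Stick retain fewer axes on synthetic data than on comparable real
  data.
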