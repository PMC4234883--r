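---
title: "Methods: topological clustering of voxel transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topological clustering of voxel transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxtome)
```

## The data model

The pipeline assumes tissue sampled on a regular grid of cubic voxels
(default pitch 50 μm), each voxel an independent RNA-seq library of roughly
one hundred cells. The primary input is a genes × voxels matrix of
non-negative integer read counts plus a layout table mapping each voxel id
to `(section, row, col)`; the listed voxels define the tissue mask, and
positions absent from the layout are background — never imputed. Grid
coordinates are 0-based; row grows downward in the rendered image (dorsal to
ventral for a coronal forebrain section), col grows laterally. Voxels
present in only one of the two inputs are dropped with a warning rather
than guessed at.

Counts are normalized to reads per million within each voxel: every
included gene's count is divided by the voxel's total over included genes
and multiplied by 10⁶. The exclusion list exists because repeat-derived
reads are conventionally removed from the scaling denominator; the
annotation defining "repeat" is protocol-specific, so it is supplied by the
user (default empty). A voxel whose included total is zero cannot be
scaled; it is set to an all-zero column with a warning instead of erroring,
since empty voxels do occur at mask edges. "Detected" gene counts use a
≥ 1 read threshold by default; the threshold is exposed because detection
is not standardized across protocols.

## The clustering construction

The goal is to group voxels by transcriptional state without assuming how
many states exist or that they are linearly separable. The construction is
the Mapper recipe from topological data analysis, with these concrete
choices:

**Metric.** Each voxel's per-million profile is z-scored across genes
(population convention, divisor *n*); the distance between voxels is
`1 − r` on the standardized profiles, where `r` is Pearson correlation.
Z-scoring per voxel makes the subsequent correlation an uncentred cosine of
z-profiles and removes per-voxel scale entirely, so the metric is invariant
to affine rescaling of any voxel's raw profile. Standardization per gene is
exposed as an option (`standardize = "gene"`), since the axis convention
differs between software traditions. `1 − r` rather than `√(2(1 − r))` is a
deliberate simplification: downstream stages consume only distance ranks,
and the two conventions are rank-equivalent on `r ∈ [−1, 1]`.

**Lenses.** The two stratifying coordinates are classical multidimensional
scaling of the distance matrix — double-centre `−D²/2`, take the top two
spectral coordinates ordered by decreasing eigenvalue. This is the "metric
SVD" construction: principal-component-like axes computed from the metric
rather than the raw matrix. Signs are fixed so each coordinate's
largest-magnitude entry is positive, making results reproducible across
linear-algebra backends. If fewer than `k` eigenvalues are positive the
function refuses and suggests a smaller `k`.

**Cover.** Each lens axis gets `resolution` base intervals holding equal
voxel counts (±1), with ties broken stably by voxel index; interval
boundaries sit midway between adjacent quantile groups. Each base interval
is then expanded about its centre to `gain` times its width, so a voxel
lies in about `gain` intervals per axis (never more than `⌈gain⌉ + 1`).
The defaults — resolution (40, 30), gain (2.5×, 4×), equalized — are the
analysis parameters the pipeline is built around. A relative tolerance of
10⁻⁹ on interval edges guards against floating-point exclusion of boundary
voxels; the 2-D cover is the Cartesian product of the two interval lists,
and every voxel provably lands in at least one product bin.

**Within-bin clustering.** Members of each product bin are clustered by
single linkage on the restricted distance matrix. The dendrogram is cut by
the standard first-gap heuristic: merge heights are histogrammed over
`[0, max height]` in 10 bins, and the cut sits at the lower edge of the
first *empty* bin that follows a non-empty one. Requiring a preceding
non-empty bin matters: when all pairwise distances are equal the histogram
mass sits in the last bin and a naive "first empty bin" rule would shatter
the bin into singletons, whereas no gap has actually been observed — the
correct reading is a single cluster. Singletons and two-member bins
likewise form one cluster, as one merge height cannot exhibit a gap.

**Nerve.** One node per (bin, in-bin cluster); an undirected edge joins two
nodes exactly when their member sets intersect, weighted by the shared
voxel count. This is a structural definition with no tunables; the tests
verify it against brute-force set intersection.

**Segmentation.** The nerve is first decomposed into fine communities by
deterministic greedy modularity optimisation on the weighted graph. On
covers this fine, the nerve is deliberately over-resolved: it typically has
dozens of communities and several disconnected components, so no
graph-only method can decide that two distant islands carry the same
transcriptional state. The fine communities — groups of samples already
merged by the cover — are therefore clustered on their expression:
average-linkage agglomeration of the mean pairwise correlation distance
between community voxel sets. With a requested `k` the tree is cut at `k`;
automatically, the cut sits just below the largest jump in merge height,
the natural reading of "clusters separated by a distance gap". Every voxel
then takes the majority label over the nodes containing it; ties go to the
cluster holding the largest node, then the lowest cluster index. When no
distance matrix is supplied to `segment_nerve()` the fine communities are
used directly, with weight-guided merging or recursive splitting to reach a
requested `k` — useful for inspecting the raw graph structure, but the
distance-refined path is what `run_mapper()` uses.

The whole pipeline is deterministic: no stage consumes random numbers, and
a seed argument exists only to future-proof stochastic segmentation
plug-ins.

## Marker detection

Each cluster is compared against the pooled remaining voxels, gene by gene,
with the two-sample Kolmogorov–Smirnov statistic evaluated at all pooled
unique values, so heavily tied count data are handled exactly. P-values use
the exact conditional distribution when `n·m ≤ 10,000` (the conventional
cutoff) and the asymptotic Kolmogorov distribution at effective size
`nm/(n+m)` otherwise. The exact-method range matters: at the sample sizes a
marker screen actually meets, the asymptotic far tail — precisely where
Bonferroni thresholds live — is unreliable.

Bonferroni correction defaults to the full screen, genes × clusters,
because the α = 0.05 guarantee is meant to cover the entire marker search:
with per-cluster families the union bound degrades to `alpha × n_clusters`.
The per-cluster family remains available (`family = "per_cluster"`) for
users who deliberately interpret each cluster comparison as its own
experiment. On tied counts the KS statistic is discrete, making the
p-values conservative (sub-uniform under the null) — the family-wise error
rate of the screen is therefore somewhat below its nominal level, which the
acceptance script estimates empirically.

Markers run on per-million values, matching the units of the expression
images; KS is invariant under strictly increasing transforms, so for
equal-depth voxels the choice of raw versus normalized input is
inconsequential. The export filter keeps significant genes with KS score
strictly above 0.25, the operating point for downstream functional
enrichment; "KS score" here is simply the statistic `D`.

## Spatial back-projection

A voxel image is one pixel per voxel over the bounding box of a section's
mask — no interpolation, smoothing, or upsampling beyond block replication
at render time, because the images are measurements, not illustrations.
Continuous images scale to the per-image maximum by default (a fixed range
is available for cross-gene comparison) through a 256-level inferno ramp;
categorical images use the Okabe–Ito palette; background is black. The
cluster projection reports, per label, the number of 4-connected components
inside the mask: a compact summary of whether a transcriptional cluster is
also a spatial region. 4-connectivity is the stricter choice and matches
the raster's edge-sharing notion of contiguity.

## The synthetic generator

`generate_fixture()` draws data under the regime the pipeline assumes: a
wedge-shaped mask (~130 voxels on the default 16 × 12 grid, the size of a
large section) split into four dorsoventral bands of near-equal voxel
count; five expression programs with program 1 in the dorsal
(ventricular-zone-like) band, 2 and 3 in successive bands, and 4 and 5
interleaved voxel-by-voxel (Bernoulli ½) within the ventral band —
reproducing the situation where two transcriptionally distinct states share
one spatial territory. Gene baselines are log-normal(0, 1); each program
amplifies its 200 marker genes 4-fold (log₂ effect 2); per-voxel means are
rescaled to a log-normal library size (median 14,000 reads over 2,000
genes, preserving per-gene read depth when the study-scale gene panel is
shrunk to desk size); counts are negative-binomial with size 10 and a 5%
dropout zeroing. The noise choices reflect that a ~100-cell voxel behaves
like a miniature bulk sample — modest overdispersion, little dropout — not
like a single cell. At these defaults a direct hierarchical clustering of
the distance matrix recovers the planted programs essentially perfectly, so
pipeline recovery failures measure the pipeline, not an impossible task.

`generate_null()` strips all structure (i.i.d. voxels) and returns a fixed
round-robin 4-way partition for family-wise-error experiments. Recovery is
scored by the adjusted Rand index, computed from the contingency table by
the standard permutation-model formula.

What the generator does *not* emulate: multi-section/multi-animal batch
structure, spatial autocorrelation within a band beyond the program itself,
gradients (programs switch at band boundaries rather than fading),
cell-type mixtures within a voxel, and protocol artifacts such as
amplification bias. Passing the recovery tests therefore demonstrates that
the implementation is correct and that banded programs of realistic effect
size are recoverable — not that the pipeline succeeds on any real tissue.

## Problem sizes and runtime posture

The shipped experiments are desk-scale by design: recovery runs the full
pipeline on 20 seeded fixtures of 125 voxels × 2,000 genes; the error-rate
simulation uses 200 null replicates of 100 voxels × 2,000 genes; oracle
checks (nerve vs brute force, KS vs pooled-ECDF enumeration, MDS vs planar
configurations) use thousands of small random instances. These sizes make
the whole validation suite runnable in minutes on a laptop while keeping
every statistical claim an actual computation.

## Known limitations

- The automatic cluster count comes from a single largest-gap rule on the
  agglomeration heights; data with a hierarchy of comparable gaps will
  resolve at whichever gap is largest, which may not be the biologically
  interesting level. Passing `k` overrides it.
- Equalized covers assume enough distinct lens values per axis
  (`resolution` ≤ distinct values); extremely degenerate data should use a
  lower resolution.
- The GEO series-matrix loader targets a processed genes × samples table;
  it does not fetch or decompress archives.
- Sections are treated independently in imaging; there is no 3-D
  reconstruction across serial sections.
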