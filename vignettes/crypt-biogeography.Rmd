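---
title: "Methods: quantifying the spatial structure of crypt-associated microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the spatial structure of crypt-associated microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptscape)
```

`cryptscape` analyzes 3D fluorescence imaging of the intestinal mucosa in
which bacterial taxa are labelled on their 16S rRNA (HCR-amplified FISH)
and each epithelial crypt is treated as one volumetric unit hosting a
bacterial community. This vignette is the package's account of the models
it implements, the assumptions behind them, and the choices made where the
methodology was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## From voxels to crypt records

**Spectral unmixing.** Multiplexed imaging detects several fluorophores in
overlapping emission windows. With a detection-channel × fluorophore
weight matrix $S$ (columns normalized to unit sum), the observed spectrum
$m$ of each voxel is modelled as $m = S a + \varepsilon$ and solved by
ordinary least squares; negative components are clamped to zero and the
residual norm $\lVert S\hat a - m\rVert$ is kept as a per-voxel QC map.
Clamp-after-least-squares was chosen over constrained optimization because
it is exact for well-conditioned spectra, orders of magnitude cheaper, and
its failure mode (large residuals) is visible in the QC map. A
rank-deficient $S$ is rejected with the collinear fluorophores named.

**Segmentation.** Bacterial aggregates are the 26-connected components of
the super-threshold mask of one channel (6-connectivity available), with
components below `min_voxels` discarded. The threshold is user-supplied:
the commercial software used in the motivating workflow does not publish
its parameters, so no default could be justified. Centroids are unweighted
(binary-mask) centroids by default — "center of mass" in this literature
does not specify intensity weighting — with weighted centroids as an
option recorded in the output metadata. Physical coordinates follow
`(index − 1 + 0.5) × voxel_size` (R indices are 1-based; voxel centers, not
corners), so a centroid can never leave its object's bounding box.

**Crypt assignment and depth.** Objects are assigned to the crypt whose
axis (a vertical line through the crypt center, by default) is laterally
nearest, within that crypt's radius; exact ties go to the smaller crypt id
so runs are reproducible. A taxon's *center-of-mass depth* in a crypt is
the voxel-count-weighted mean of its objects' axial positions minus the
luminal opening plane; larger is deeper. The pairwise offset
$\Delta CM(A, B) = d_A - d_B$ is signed (positive = $A$ deeper), which
makes antisymmetry and the triangle identity exact; distributions of
$\Delta CM$ centered on zero indicate colocalization, skew indicates depth
segregation. Depth is undefined (NA, excluded downstream) for a taxon with
zero voxels in a crypt.

## Tissue-scale metrics

**Colonized-crypt density** tiles the (x, y) plane into half-open squares
of edge 425 µm — the side of one 20× confocal field, which holds on the
order of 20 cecal crypts — anchored at the sample bounding-box minimum,
and reports the mean ± SD of colonized crypts per non-empty tile. Real
acquisitions count crypts per microscope tile; the post-hoc grid is an
approximation of that and is documented as such. A crypt counts as
colonized when its eubacterial voxel count reaches `colonization_min`
(default 1; the literature leaves "colonized" undefined).

**Spatial clustering** takes the connected components of the graph joining
crypt centers at (x, y) distance ≤ 150 µm, about twice the typical
distance between contiguous crypt centers. The two source descriptions of
this rule disagree on the comparator (≤ versus <); the package defaults to
≤ and exposes `comparator = "lt"`. Cluster sizes are summarized *per
crypt* (each crypt weighted by its own cluster's size; 12.5/50/87.5th
percentiles give the median and central-75% interval), matching the "75%
of crypts in clusters between …" phrasing; per-cluster quartiles are
reported alongside. The production path uses grid-bucketed union-find; the
test suite proves it equal to a brute-force $O(n^2)$ oracle.

## Community typing

Per-crypt taxon voxel counts are Z-scored per taxon (sample SD, $n-1$;
zero-variance taxa map to all-zeros and are flagged), making channels with
very different dynamic ranges comparable as enrichment scores. Crypts are
clustered by cosine distance $1 - \cos(u, v)$ with average linkage
(UPGMA) — the standard companion to cosine distance in heat-map HCA; the
linkage was not specified by the motivating analysis, and `complete` and
`ward.D2` are available and recorded in output metadata. The tree is cut
at exactly $k$ groups ($k = 6$ by default: the "six most prominent
branches" was operationalized as a fixed $k$ rather than a fixed height,
since "most prominent" is not otherwise computable) and labels A, B, …
are assigned by cluster size descending, ties toward the smallest member
index, so two runs agree exactly. A crypt whose Z-profile is exactly zero
has no cosine direction; when the Z matrix is passed to `cut_tree` such
crypts are reassigned to the nearest (Euclidean) type centroid and
flagged.

Silhouette scores use the same cosine distance;
$s(i) = (b - a)/\max(a, b)$ with singletons scored 0 and the $a = b = 0$
degenerate case scored 0. Clustering quality is also checked against
ground truth with the adjusted Rand index on synthetic data.

**Nearest-neighbor type analysis.** For each crypt $i$ and target type
$T$, $d(i, T)$ is the distance to the nearest crypt of type $T$ (excluding
$i$); entry $(S, T)$ of the reported matrix is the median of $d(i, T)$
over crypts of type $S$, so the diagonal uses each crypt's nearest *other*
member of its own type and is NA for singleton types. Type A (unenriched
in every taxon) is excluded by default — entirely, i.e. before any
distances are computed; keeping it as a target is a documented toggle. A
one-sided label-permutation test on (median same-type NN distance − median
cross-type NN distance) assesses whether like types aggregate spatially.

## Group statistics

The Wilcoxon rank sum test uses midranks; when both groups have ≤ 10
observations and the pooled sample is tie-free the two-sided p-value is
exact by full enumeration of $\binom{n_1+n_2}{n_1}$ rank assignments,
otherwise a tie-corrected normal approximation with continuity correction
is used (the original analyses do not say which their software chose, so
the method actually used is reported with every result).
Benjamini–Hochberg is the standard step-up at FDR 0.1 (0.25 where noted in
the absolute-abundance display); flags are provably monotone and the tests
compare them to a brute-force evaluation of every cutoff. Box summaries
use type-7 (linear interpolation) quantiles and 1.5 × IQR fences — both
recorded because the cluster-size percentiles depend on the interpolation
rule. Absolute family abundances multiply the total 16S load by sequencing
proportions; the zero → one substitution exists *only* in the log-display
column, never in stored data, to prevent silent corruption.

## The synthetic mucosa generator

The generator is first-class, tested code: it states a world with the
statistical structure the analyses assume and hands the analyst complete
ground truth (true types, seed lineages, spatial-cluster labels, per-object
voxel lists). Its defaults are fixed once and are not tuned against test
outcomes.

- **Lattice**: hexagonal packing at pitch 75 µm (half the 150 µm
  clustering threshold, which is described as twice the typical
  inter-crypt distance; the true pitch is not published, so it stays
  configurable, with a square grid option), with Gaussian positional
  jitter (default SD 5 µm).
- **Colonization**: a seed-and-spread contact process — Bernoulli seeds
  (default 5%), then for 3 rounds each colonized crypt colonizes each
  empty neighbor within 1.5 × pitch with probability 0.5. The motivating
  observations describe patchiness, not a mechanism; this is the simplest
  generator with tunable clustering. Each crypt records the seed lineage
  that colonized it.
- **Types**: six abundance archetypes over Bacteroidetes, Clostridia and
  Bacilli mirror the reported enrichment pattern (A unenriched; B
  Clostridia; C and F Bacilli, C with Clostridia co-enrichment; D
  Bacteroidetes + Clostridia; E Bacteroidetes), with magnitudes in the
  hundreds of voxels, the scale of reported segmented colony volumes.
  Seeds draw a type from a uniform prior; a spread-colonized crypt copies
  its source's type with probability `type_spatial_coupling` (default
  0.9), which plants the spatial aggregation of like types that the NN
  analysis detects.
- **Abundances**: multiplicative lognormal noise on counts,
  $\mathrm{round}(\exp(\log(\mu + 1) + \mathcal N(0, \sigma))) - 1$
  clamped at 0 (default $\sigma = 0.3$); counts are non-negative and span
  orders of magnitude, and the construction keeps the sample median at the
  archetype mean. Taxa with archetype mean zero stay exactly zero — the
  literal formula can produce spurious counts from pure noise, so absence
  is preserved by an explicit clamp (recorded as a deliberate deviation).
- **Depths**: truncated Gaussians per taxon on [0, crypt depth 80 µm];
  defaults Bacilli 15, Clostridia 30, Bacteroidetes 45 µm (SD 5 µm),
  reproducing the shallow-Firmicutes / deep-Bacteroidetes stratification
  with a 30 µm Bacilli–Bacteroidetes offset.
- **Rendering**: 7-voxel blobs at intensity 100 on an isotropic 1 µm grid,
  resampled so blobs stay > 1 voxel apart (sparse scenes are therefore
  exactly segmentable; crowded crypts flag `crowded`), mixed through the
  channels × fluorophores matrix and degraded with additive Gaussian
  noise. Ground-truth voxel lists are recorded before mixing and noise.
- **Gel slabs**: cells at uniform depths in 0–600 µm; stained with
  probability `efficiency(depth)` (S/B ratio lognormal around 200), else
  background-level (ratio ≈ 1), emulating depth-limited lysozyme
  permeabilization.
- **Randomness**: one integer master seed feeding fixed per-stage
  sub-streams, so adding draws to one stage never perturbs another and
  every output is bit-reproducible.

**What a green test does and does not establish.** The generator emulates
the *statistical* structure of the real data — patchy colonization,
type-structured compositions, depth stratification, spectral bleed-through,
depth-dependent staining — not its optics: there is no PSF, no refractive
aberration, no mucus or host-nuclei background, no anisotropic sampling by
default, and blob geometry is idealized. Green acceptance tests establish
that the estimators recover a known world correctly at realistic magnitudes;
they do not re-derive any published biological value, because those derive
from deposited imaging data that are not recomputable at desk scale.

## Interpretation notes on the stated invariants

Two properties that sound absolute hold only in qualified form, and the
package tests the qualified versions:

- *Spread vs. matched random colonization.* At the default densities the
  colonized fraction reaches ~40%, where a Bernoulli control percolates on
  the ≤ 150 µm (second-shell) graph and forms one giant cluster; the
  spread process then has the *smaller* mean cluster size. The
  clustering-from-spreading signal is real on the contact graph
  (first-shell, 1.5 × pitch), and that is where the property is tested.
- *Type purity under full coupling.* With `type_spatial_coupling = 1`
  every crypt inherits its seed's type, so each seed lineage is pure; but
  two independently seeded patches with different types can grow within
  150 µm of each other and merge into one spatial cluster. The tested
  invariant is the mechanism-level one: types are constant within
  lineages, and a mixed cluster always contains seeds of unlike types.
- *Community-type recovery.* "ARI ≥ 0.8 over 20 seeds" is evaluated as the
  mean ARI across seeds at the stated world (noise SD 0.3, n = 300,
  k = 6, average linkage); individual seeds range either side of the mean
  because average linkage occasionally splits one archetype and merges two
  sparse ones.

## Numerical conventions and degenerate inputs

Voxel indices are converted to physical µm at voxel centers; depth is
measured along +z from the luminal opening plane (z = 0 by default). The
half-open tiling rule places a crypt at exactly x = 425 (anchor 0) in the
second field. Empty colonization sets, empty crypts, sub-threshold
volumes, singleton types and zero vectors all return defined, flagged
results rather than errors wherever the downstream analysis can proceed;
errors are reserved for contract violations (unknown taxon or channel,
single-row Z-scoring, k > n, no eligible QC cells, rank-deficient
spectra, probability/threshold range violations). TSVs are written with
missing values as empty strings so the literal condition label "NA"
(unexposed to antibiotic) survives round-trips, and numeric columns at 15
significant digits so fixed-seed pipelines reproduce files byte for byte.

## Known limitations

- No TIFF/OME-TIFF I/O: no R TIFF reader is available in the supported
  environment, so volumes are in-memory arrays with a JSON text
  serialization intended for small fixtures and CLI round-trips.
- Segmentation is a global intensity filter; adaptive or learned
  segmentation, PSF deconvolution and tile stitching are out of scope.
- The field-of-view grid approximates acquisition tiles; densities from
  real tiled acquisitions may differ near sample borders.
- `nn_type_distances` is $O(n^2)$ in colonized crypts; fine for the
  hundreds of crypts typical per sample.
- Ordination (PCoA), t-SNE/UMAP verification plots, qPCR calibration and
  sequencing read processing are deliberately not reimplemented.
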