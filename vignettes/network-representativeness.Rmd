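---
title: "Methods: representativeness and constituency of site networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representativeness and constituency of site networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siterep)
```

## The model

A site network is a set of named sites, each holding one or more
experimental centroids (points, or the area-weighted centroids of
experimental-field polygons). The landscape is a stack of co-registered
single-band rasters of environmental drivers — climate normals, soil
properties, topographic indices — with a shared validity mask (a cell must
be valid in *every* layer to enter any statistic; this is the strictest
possible nodata rule, chosen because a cell with a missing driver has an
undefined position in the feature space).

Because driver layers are correlated and carry incommensurable units, all
distances are measured in a principal-component feature space. `fit_pca()`
centers and (by default) scales the layers over valid cells and decomposes
them by SVD; `select_components()` keeps the smallest leading set of
components reaching a cumulative explained-variance threshold (default
0.90). Scaling to unit variance is the default because an unscaled
decomposition would be dominated by whichever layer happens to have the
largest numeric range; the flag remains for stacks already on a common
scale. A deterministic sign convention (the largest-magnitude loading of
each component is positive) makes outputs reproducible across linear
algebra backends. Whether the PCA should be fit on all valid cells or only
on masked (working-lands) cells is genuinely open; the package fits on all
valid cells, so the feature space describes the whole landscape and masks
only restrict *reporting*, not geometry.

Representativeness of a centroid at a cell is

\[ r = 1 - \frac{\lVert V^{site} - V^{pixel} \rVert}{D} \]

with \(V\) the selected-component score vectors and \(D\) a normalization
constant. Per-site layers aggregate a site's centroid maps (cellwise
maximum by default), and the network layer is always the cellwise maximum
over *all* centroids: each cell reports its single best match anywhere in
the network. Constituency assigns each masked cell to the site whose
per-site value is highest there — an exhaustive argmax with ties broken
toward the earlier-listed site and no spatial smoothing of any kind, so any
spatial coherence in the constituency map is inherited from the spatial
autocorrelation of the drivers, not imposed.

## Choices the definition leaves open

**The divisor `D`.** The index is only defined up to the choice of
normalization. The package default is the feature-space bounding-box
diameter over valid cells: the Euclidean norm of the vector of
per-component ranges. Three properties recommend it: it depends only on the
landscape (never on the site set), so adding a site can never lower any
cell's value and different networks are measured on one scale; it bounds
every centroid-cell distance, so \(r \in [0,1]\) without meaningful
clipping; and it is cheap (one pass). The alternative `observed_max` — the
exact maximum (centroid, cell) distance — reproduces a normalization tied
to a particular network; it is available for fidelity experiments but makes
cross-network comparison incoherent, which is why `best_network_map()`
expects a shared bounding-box constant.

**Site aggregation.** Summing a site's centroid maps produces values
outside [0, 1] that cannot agree with a max-based network layer; the
package therefore defaults to the cellwise maximum, which makes the
per-site layers, the network layer and the constituency argmax mutually
consistent (the winner's value *equals* the network value everywhere — an
invariant the tests assert). `"mean"` and `"sum"` are provided; `"sum"`
warns that its output is not a normalized representativeness.

**Absolute value in the index.** A root of a sum of squares is already
non-negative, so the absolute-value bars sometimes written around it are
redundant and are not implemented.

**Cell membership.** A point on a shared cell edge belongs to the cell to
its east/south (west/north edges inclusive), implemented as a floor on
fractional indices. Centroids outside the grid are a hard error (they
indicate mis-registration), while centroids on invalid cells are dropped
with a counted warning — missing data, not a geometry bug.

## The synthetic landscape generator

`generate_fields()` builds stationary Gaussian random fields by spectral
synthesis: white noise is filtered in the Fourier domain with a
squared-exponential low-pass with e-folding scale `correlation_length`
(default 12 cells on the default 128-cell domain), inverse-transformed, and
standardized. The squared-exponential filter gives smooth, mean-square
differentiable surfaces like interpolated climate normals; the FFT route is
fast and exactly seeded, at the accepted cost of periodic boundary
artifacts. Cross-layer correlation is imposed by multiplying with the
symmetric square root of the target correlation matrix (negative
eigenvalues clipped at zero, tolerating near-PSD input), and each layer is
re-standardized afterwards, which leaves correlations untouched.

The default cross-correlation is compound symmetry with pairwise r = 0.9:
a single dominant environmental factor — think of a temperature–moisture
continuum — plus layer-specific noise. This gradient-dominated regime is
what makes constituencies behave like ecoregions anchored at sites, and it
was chosen (together with the correlation length and the 2-cell centroid
jitter) so that the planted-structure property holds by design: when four
sites are placed stratified along the dominant feature-space gradient, the
inner half of each stratum is assigned back to its own site. An
autoregressive alternative (`ar1_cross_corr()`, lag-1 r = 0.78, whose
15-layer eigenvalue spectrum puts seven components near 90% of variance,
similar to real bioclimatic/edaphic stacks) is provided for experiments
with richer spectra; independent layer variance then dilutes the gradient
and weakens the ecoregion-like structure, which is a property of such
landscapes, not a defect of the method.

`generate_mask()` thresholds a latent layer at its realized quantiles, so
configured class proportions are hit exactly and patches inherit the
latent field's spatial coherence. Default proportions (35% non-working,
44% grazingland, 19.5% cropland, 1.5% mixed) follow the approximate CONUS
shares of those land uses. `generate_network()` places site anchors either
at random valid cells or stratified — one anchor per quantile stratum of a
designated layer, at the stratum's *environmental prototype* (the valid
cell nearest the stratum's component-wise median vector), which is how a
designed network would pick a typical site for each stratum. Centroids are
Gaussian-jittered around the anchor with bounded redraws onto valid cells;
the default network (18 sites of 5–50 clustered centroids) mirrors the
scale of a national agroecosystem network. Seed substreams are documented
in `pipeline_config()`: the landscape uses the master seed, the home
network seed + 1, sister network *i* seed + 1 + *i*.

What the generator does **not** emulate: real geography (coastlines,
mountain ranges, anisotropy), non-Gaussian drivers, heavy-tailed or
categorical layers, non-stationary correlation structure, and real site
placement politics. Passing tests therefore demonstrate the *method's*
correctness and invariances, not field performance on any particular real
landscape.

## Numerical contract

All distance accumulation is in double precision, component by component,
cell-independent; tiled processing (`tile` raster rows per block) therefore
reproduces the untiled result bitwise, which the tests assert at 1e-12 and
in practice observe exactly. Distances are computed by direct summation of
squared component differences (not by expanding cross products), avoiding
cancellation; oracle-equivalence tests run at 1e-12. A centroid's own cell
has distance exactly zero and representativeness exactly 1 — floating
point included — because no arithmetic intervenes. Clipping to [0, 1] can
trigger only at floating-point edges under the bounding-box divisor and is
counted and reported. Degenerate inputs fail loudly: zero-variance layers
cannot be standardized, an all-identical feature space has no defined
normalization, empty class selections and empty networks are errors rather
than empty results.

Quantiles use the R default (type 7); kernel densities in
`summarize_by_class()` use a Gaussian kernel with Silverman's rule-of-thumb
bandwidth. Mask thresholds given explicitly must be strictly increasing;
collapsing all mass into one class is legal (a single-class mask), a
constant latent layer warns.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
landscapes: oracle comparisons on 6–12 cell grids where exhaustive double
loops are feasible, invariance and recovery checks at 64–128 cells
squared with the default 15-layer stack and 18-site networks (roughly 500
centroids, i.e. ~8 million centroid-cell comparisons per map), all of
which complete in seconds on one CPU. The method itself is linear in
(cells x centroids x components) and the tiled contract keeps memory flat,
so continental grids are a matter of wall time, not algorithm.

## Known limitations

* No reprojection: all inputs must already share one grid; the package
  checks and refuses rather than warps.
* Raster I/O is the portable ASCII grid dialect (plus GeoJSON vectors and
  YAML tables); binary raster formats are out of scope.
* The generalist/specialist/double-duty labels are conventions over
  configurable thresholds (median area split, 0.8 representativeness
  floor, 0.2 lower-tail gap), intended as a triage aid, not as measured
  ecological categories.
* Ranked constituency lists are kept top-N (default 3) to bound output
  size.
* Representativeness is blind to anything outside the driver stack:
  management, socio-economics, and biotic context are not part of the
  feature space.
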