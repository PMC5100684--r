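---
title: "Dense neuronal reconstruction from SBEM volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense neuronal reconstruction from SBEM volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbemtools)
```

# Scope

Serial block-face scanning electron microscopy (SBEM) images a tissue
block by repeatedly cutting away an ultrathin section (here 25 nm) and
scanning the freshly exposed face, producing an anisotropic image stack
(voxels of 9.25 x 9.25 x 25 nm). Each section is acquired as a mosaic of
overlapping camera tiles, neurons are reconstructed by manually placing
connected nodes along neurites ("skeletons"), and each neuron is traced
several times independently so that a consensus procedure can detect and
correct tracer errors.

`sbemtools` implements the computational core of that workflow:

1. per-section tile registration and stitching,
2. a chunked ("cubed") multi-resolution volume store with dynamic
   neighborhood loading and trilinear oblique reslicing,
3. the NML/NMX skeleton annotation formats,
4. CORE consolidation of redundant tracings with mismatch detection and
   error correction,
5. glomerular innervation morphometry and length-based reconstruction
   accuracy metrics.

Everything is exercised against seeded synthetic fixtures with known
ground truth; no microscope data is required.

# Tile registration

## Model

Tile distortions are negligible at small tile sizes, so registration is
purely translational. For a pair of overlapping tiles the displacement
is estimated as the argmax of the 2-D cross-correlation of the
*standardized* images (columns standardized to zero mean and unit
variance, then rows), computed in the Fourier domain and restricted to a
central window of the correlogram corresponding to a maximal expected
offset (default 256 pixels, matching the acquisition overlap of 5-8 %).
Standardization removes illumination gradients so the peak reflects
texture. No sub-pixel refinement is applied; offsets are integer pixels.
Ties in the correlation peak are broken by the smaller offset norm, then
lexicographically, so the estimator is deterministic.

The FFT computation zero-pads the standardized images (their mean is
zero, so zero-padding is mean-padding) far enough that circular
correlation equals linear correlation inside the search window; the
estimator is therefore *exactly* equal to exhaustive spatial-domain
cross-correlation, which the test suite verifies by enumeration at
window sizes up to 64 on 256-pixel tiles.

Given all pairwise offsets of a section, tile positions minimize the sum
of squared displacement residuals
`sum || (p_j - p_i) - d_ij ||^2` over measured pairs -- a global
least-squares placement solved per coordinate as a sparse normal system,
with one anchor tile fixed at the origin to remove the translational
gauge freedom. Whether the original pipeline weighted pairs by
correlation quality is not documented; the solver is unweighted by
default with an optional `weight` column (e.g. peak scores). For
consistent offsets the residuals are zero and the solution equals
spanning-tree accumulation; for noisy offsets the least-squares
averaging brings the position RMSE below the offset noise, which the
suite checks empirically over 20 seeds.

## Contrast normalization

Acquisition is 16-bit; storage and annotation use 8-bit. A Gaussian is
fitted to the dominant mode of the intensity histogram and the linear
map sending `peak - k*sigma -> 0` and `peak + k*sigma -> 255` (clipped,
rounded half-up) converts to 8 bit; `k` defaults to 2 within the
conventional 1.5-3 range. The exact histogram estimator used originally
is not documented; here the fit is nonlinear least squares restricted to
+/- 3 MAD around the histogram mode with the extreme bins excluded,
which keeps dark-axon/silver-particle tails and saturated pixels from
biasing the fit. On a synthetic N(30000, 1000) image the fitted
parameters are recovered to within +/- 20 intensity units, and 10 %
uniform outliers move the peak by less than sigma/10.

Stitching pastes tiles at their rounded positions; the default blend is
last-writer-wins, which keeps single-coverage pixels bit-exact (the
property the tests rely on), with optional linear feathering. A
provenance mask records the contributing tile per pixel.

# Cubed volume store

Volumes are divided into fixed-edge 8-bit cubes (default 128 voxels,
arbitrary edges supported), one raw file per cube under
`level/x####/y####/z####/cube.raw` in x-fastest order with a plain-text
`.conf` geometry file -- a seekable layout in the KNOSSOS lineage.
Boundary cubes are zero-padded so all reads are fixed-size. A lost
section is recorded as a z-gap in the metadata; no interpolated imagery
is fabricated.

Zoom levels halve each axis (`ceiling(dim / 2^l)`) by 2 x 2 x 2 mean
pooling with half-up rounding; partial boundary blocks average only the
voxels that exist. The downsampling factor and filter are not documented
for the original store; factor 2 with mean pooling is the de facto
convention for such pyramids.

Interactive browsing loads a cubed neighborhood (typically 320-576
voxels) around the focal point, at the zoom level in use and its two
neighbors, with the focal point rescaled per level. The cache is hybrid:
every cube fetched from the backing source is written through to a
persistent disk cache (each cube is fetched at most once, and previously
visited regions remain browsable offline), while memory residency is
bounded by a byte budget with least-recently-used eviction. The test
suite checks the resident set against a brute-force cube/box
intersection oracle and asserts that repeat loads perform zero backing
reads.

Oblique views sample a plane `center + i*pitch*u + j*pitch*v` by
trilinear interpolation, converting nm to voxel indices with the
anisotropic pitch (times `2^level`). Voxel coordinates follow the
corner convention (`nm = index * pitch`, 0-based internally). Trilinear
interpolation is exact on trilinear fields, which gives an analytic
correctness check: a reslice of a linear-ramp volume equals the ramp at
the sample points to 1e-6. Samples outside the stack are zero.

# NML and NMX annotation IO

NML is an XML dialect: a `things` document whose `thing` elements hold
`nodes` (attributes `id, x, y, z, radius`) and `edges`, with node-level
`comments` and a `parameters/scale` element carrying the voxel pitch in
nm. File coordinates are 1-based voxel indices; the package uses 0-based
indices internally, a lossless conversion for integer positions.
Attributes outside the documented subset (`inVp`, `inMag`, `time`, ...)
are preserved verbatim, since the complete attribute inventory of the
original files is not documented. Output is deterministic (sorted
things, nodes, edges, comments), so serialization is byte-reproducible.

An NMX file is a zip container of NML documents (one neuron's skeleton
and soma outline per `Neuron_id<ID>.nmx`). Reading uses the standard
unzip machinery; writing uses a minimal built-in ZIP writer (store
method, CRC-32, central directory) whose output any unzip implementation
reads back.

Synapses are annotated as three connected nodes -- presynaptic neuron,
synaptic cleft, postsynaptic neuron -- with a user-defined class and an
ordinal confidence. The serialization (a 3-node, 2-edge thing with
comments `pre`, `cleft:<class>:<confidence>`, `post`) is this package's
own convention, since only the annotation semantics, not the file
encoding, is documented. Soma outlines are edge-less things holding at
least 4 non-coplanar points.

The innervation table (neurite length of each neuron in each
glomerulus) is CSV with columns `neuron_id`, `cell_type`, then one
column per glomerulus. Cell types are validated against {mitral, IN1,
IN2, IN3, UPN, LOC, other}; unknown labels map to `other` with a
warning. Lengths are micrometres (the unit in which innervation
thresholds are quoted downstream); the file header states the unit.

# CORE consolidation

## Procedure

Each neuron is traced independently three times. CORE (COnvergence by
Redundancy and Experts) consolidates the redundant tracings:

1. **Resample** every tracing to a working node density of about 100 nm.
   Implemented as per-edge subdivision: every polyline edge longer than
   the target spacing is split into equal sub-intervals. All original
   nodes (in particular branch points and endpoints) are retained and
   new nodes lie on the polyline, so arc length is preserved *exactly* --
   the bookkeeping invariant the accuracy metrics depend on. Strictly
   uniform per-branch spacing would move traced points and shorten
   polyline corners; uniformity per edge was chosen instead.
2. **Form cliques**: groups of mutually nearby nodes, at most one per
   tracing, all pairwise distances within the clique radius. Growth is
   greedy region growing along the skeletons: starting from seed nodes,
   each clique's successors are drawn from the unassigned nodes within a
   short graph distance (3 hops) of the clique's members, preferring the
   closest-in-graph, then nearest, candidate. Growing along the
   polylines rather than by pure spatial clustering prevents cliques
   from jumping between parallel neurites; the short lookahead absorbs
   small differences in node counts between tracings of the same
   neurite. A tracing with no member in the current clique may rejoin
   through a nearby unassigned node that has an assigned polyline
   neighbor. All choices are resolved by smallest distance then lowest
   (tracing id, node id), making the output deterministic and
   independent of the input order of the tracings.
3. **Refine and dissolve**: a well-formed clique has its centroid close
   to every member's own polyline. Members whose
   centroid-to-own-polyline distance is far above the population median
   (cap: `max(6 * median, 0.2 * radius)`) were paired across different
   branches and are ejected. Cliques with fewer than `min_agreement`
   members (default 2 of 3 -- majority) dissolve into *orphans*: nodes
   in no clique, the footprint of disagreement between tracings.
4. **Consolidate**: one node per clique at the member centroid, an edge
   wherever some tracing's polyline passes between two cliques
   (projecting each tracing onto the clique labels, skipping unassigned
   nodes). Two light Laplacian smoothing iterations on degree-2 nodes
   denoise the consensus; branch points and endpoints stay fixed, and at
   these node spacings the smoothing bias on smooth curves is
   sub-nanometre.
5. **Detect mismatch points**: (a) every maximal connected orphan
   component longer than a minimum length (default: the clique radius)
   is an *extra-branch* mismatch, located at the orphan node adjacent to
   a clique member -- the point of divergence; (b) wherever one tracing
   stops while at least `min_agreement` others continue past it by more
   than `2 * radius` of path length, an *early-termination* (at a
   tracing endpoint) or *missing-branch* (at an interior node) mismatch
   is raised. Orphan fragments shorter than the minimum length are
   sampling noise from unequal node counts, not structural disagreement,
   and are not flagged.
6. **Resolve**: each mismatch is decided once -- by direct expert policy
   (`keep`/`drop`) or by majority over local re-tracings (accepted if on
   average at least half the contested sample points are covered by the
   re-tracings within the clique radius). A rejected segment is deleted
   from its tracing. An accepted missing continuation is spliced into
   the short tracing from the consensus geometry, with a duplication
   guard: spliced geometry already represented by clique-assigned nodes
   is dropped, and unassigned near-duplicates (the tracing's own
   divergent copy) are replaced. An accepted extra branch is *not*
   copied into the other tracings -- copying consensus geometry between
   tracings proved unstable (parallel near-duplicates that re-trigger
   detection); instead the confirmed segment is recorded and appended to
   the final consolidated skeleton.
7. **Iterate** until no undecided mismatch remains (decisions are keyed
   by kind, tracing and location, so a settled mismatch does not
   re-trigger), with a round cap (default 50) that raises a
   non-convergence error listing the open mismatches.

## Parameters

* `target_spacing` (100 nm): the documented working density.
* `radius` (500 nm): the clique radius. The original value is not
  printed in the data descriptor; 500 nm is well above the working node
  spacing (so jitter never breaks agreement) and well below the distance
  at which distinct neurites run at these scales.
* `min_agreement` (2): majority of the three-fold redundancy.
* Early-termination threshold `2 * radius`: separates jitter-scale
  endpoint scatter from genuine truncation.

## Validation and its limits

The end-to-end check builds a ground-truth arbor (20 um total length, 3
branch points, in a 20 um box -- sizes chosen so the full 20-seed suite
runs in minutes on one CPU), perturbs it into three tracings (20 nm
positional jitter everywhere; a terminal subtree of 20 % of the length
truncated in one tracing; a 5 um spurious branch grafted onto another)
and consolidates with a simulated re-tracer that clips the ground truth
around each mismatch. Over 20 seeds the consolidated skeletons reach
mean recall and precision above 0.99 at 100 nm tolerance (worst seed
above 0.97) -- the desk-scale counterpart of keeping missing or
incorrectly annotated length below a few percent.

The synthetic arbors are self-avoiding (minimum 1.5 um separation
between non-consecutive segments): the clique radius is premised on
neurites being farther apart than the agreement radius, and an
unconstrained random walk would re-approach itself below that scale -- a
regime outside the procedure's design, where no distance-based consensus
can distinguish parallel passes. Passing these tests therefore says
nothing about tissue in which distinct processes run closer than the
clique radius, about systematic (non-independent) tracer errors, or
about error modes other than jitter, truncation and spurious branches.

# Morphometry

Glomeruli are convex hulls around manually placed 3-D points. Hulls are
built by face enumeration (every point triple whose plane has all points
on one side is a supporting plane), an O(n^4) method that is entirely
adequate for outlines of tens of points and yields the half-space
representation directly. Volumes come from fan-triangulating each face
polygon against the hull centroid; the test suite cross-checks them
against Monte-Carlo rejection sampling within three standard errors.

Neurite length per region clips every skeleton edge against the
half-spaces (parametric interval clipping): edges partially inside
contribute their exact inside fraction, making the measure additive
under edge subdivision. Voxel coordinates are scaled anisotropically
(9.25/9.25/25 nm) before clipping; published tables are in micrometres.
Whether the original tables counted partially-inside edges fractionally
is not documented; fractional clipping was chosen for exactness.
Overlapping hulls are allowed -- glomerular boundaries are not always
sharp -- so a segment may count toward several regions. A neuron's
*parent glomerulus* is the region receiving its longest neurite length;
ties break lexicographically (flagged), all-zero rows are unassigned.

Reconstruction accuracy against a reference skeleton uses length-based
measures: both skeletons are densely resampled (tolerance/4), and

* **recall** = fraction of reference arc length within the tolerance of
  the test skeleton (missed processes),
* **precision** = fraction of test arc length within the tolerance of
  the reference (wrongly traced processes),
* **relative length error** = (missed reference length + excess test
  length) / reference length.

Distances are measured from sample points to the other skeleton's
segments, so the measure does not depend on node phase. The default
tolerance is 100 nm, the CORE working density. Swapping test and
reference swaps recall and precision exactly. Only the verbal
definitions of these measures are documented; the distance-tolerance
formulation above is the package's explicit, reproducible choice.

# Synthetic fixtures

All generators are pure functions of their seed:

* **Textures**: low-pass-filtered white noise (Gaussian kernel of width
  `correlation_length`, default 4 px) scaled to 16-bit -- a unique sharp
  autocorrelation peak like membrane-rich EM texture, without EM physics
  (no charging artifacts, no section loss, no shot-noise model).
* **Tile grids**: adjacent tiles overlap by 5-8 % of the tile edge (the
  documented acquisition overlap) plus integer jitter; ground-truth
  positions are returned alongside.
* **Skeletons**: persistent random walks with side branches, every edge
  exactly `step` long, self-avoiding as discussed above.
* **Tracer errors**: i.i.d. positional jitter, removal of a terminal
  subtree (missed processes are usually short terminal branches), and
  straight grafted branches (wrongly traced processes). No node-radius
  noise is modeled.
* **Convex regions**: points on and inside a sphere, seeded with a
  scaled tetrahedron/octahedron so the hull always encloses the center.

# Numerical choices

* Offset ties: smallest norm, then lexicographic.
* 8-bit conversion rounds half-up (`floor(x + 0.5)`), not banker's
  rounding, so the histogram midpoint maps to 128 deterministically.
* Pyramid pooling rounds half-up; a 0/255 checkerboard averages to 128.
* Degenerate standardization inputs (zero-variance rows/columns) become
  zeros with a warning, not an error; all-zero images are rejected by
  the offset estimator as signal-free.
* Hull construction uses a relative tolerance (1e-9 of the point-cloud
  extent) for face tests; coplanar inputs are a geometry error.
* The iteration cap, clique radius, agreement threshold and smoothing
  count are all exposed as arguments; the defaults above are used
  throughout the test suite.

# Known limitations

* Registration is strictly translational -- no elastic or rotational
  correction, matching the acquisition regime it models.
* The cube store is lossless raw; the original streaming service's JPEG
  re-encoding is out of scope, as is any server implementation.
* CORE's expert is an injectable callback; there is no interactive
  review tool, and no image-based (automatic) tracing.
* Cell-type classification is treated as given labels; the clustering
  that produced the interneuron classes is out of scope.
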