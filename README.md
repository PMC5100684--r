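# sbemtools

Computational building blocks for dense neuronal reconstruction from
serial block-face scanning electron microscopy (SBEM) volumes — the
image-processing and annotation-handling core of a connectomics
workflow, for people who stitch EM sections, browse cubed volumes,
trace neurons redundantly and need consensus skeletons with quantified
accuracy.

SBEM cuts ~25 nm sections from a resin-embedded block and scans the
exposed face, giving an anisotropic stack (here 9.25 × 9.25 × 25 nm³
voxels) in which each section is a mosaic of overlapping camera tiles
(5–8 % overlap). Neurons are reconstructed as skeletons — 3-D nodes
connected by edges — by several independent tracers, and the redundant
tracings are consolidated into one corrected skeleton.

The package implements:

* **Tile registration** — column-then-row standardization, translational
  offset estimation as the argmax of the FFT cross-correlogram inside a
  ±256 px window (`estimate_offset`), global least-squares tile
  placement minimizing `Σ‖(p_j − p_i) − d_ij‖²` (`solve_layout`),
  Gaussian-histogram 8-bit contrast normalization (`fit_contrast`,
  `normalize_contrast`), and mosaic assembly (`stitch`).
* **Cubed volume store** — 128³ (or arbitrary) 8-bit cubes under
  `level/x####/y####/z####/cube.raw` with a `.conf` geometry file,
  mean-pooled zoom pyramid, neighborhood loading around a focal point
  with a persistent disk cache and LRU memory budget, and trilinear
  reslicing at arbitrary plane orientations (`build_cubes`,
  `build_pyramid`, `read_subvolume`, `load_neighborhood`,
  `reslice_plane`).
* **NML/NMX annotation IO** — the XML skeleton dialect and its
  zip-container, including synapse triplets (pre → cleft → post, with
  class and confidence), soma outlines, and the neurite-length-per-
  glomerulus CSV (`parse_nml`, `write_nml`, `read_nmx`, `write_nmx`,
  `read_innervation_csv`).
* **CORE consolidation** — resampling tracings to ~100 nm node density,
  clique formation across tracings by distance and connectedness,
  consolidated-skeleton construction, mismatch-point detection
  (extra branch / missing branch / early termination) and iterative
  resolution by local re-tracings or expert decision (`resample`,
  `form_cliques`, `consolidate`, `find_mismatches`, `resolve`,
  `core_iterate`).
* **Morphometry** — convex-hull glomerulus geometry with exact segment
  clipping, innervation tables, parent-glomerulus assignment, and
  length-based accuracy metrics: recall (missed processes), precision
  (wrongly traced processes) and the relative length error
  (`build_hull`, `neurite_length_in_region`, `build_innervation_table`,
  `parent_glomerulus`, `reconstruction_metrics`).
* **Synthetic fixtures** — seeded generators for textured tiles with
  known offsets, tile grids, branching skeletons, tracer-error
  perturbations and convex regions (`gen_texture`, `gen_tile_pair`,
  `gen_tile_grid`, `gen_skeleton`, `perturb_skeleton`,
  `gen_convex_region`), so every function can be validated against
  ground truth.

A thin command-line wrapper with `simulate`, `stitch`, `cube`,
`consolidate`, `innervate` and `metrics` subcommands is installed at
`system.file("exec", "sbemtools", package = "sbemtools")`.

## Worked example

Register a synthetic tile pair with a known displacement, then
consolidate three perturbed tracings of a known arbor and measure the
result:

```r
library(sbemtools)

# -- registration: 1024x1024 tiles displaced by (69, 66) pixels
tex  <- gen_texture(1200, 1200, correlation_length = 4, seed = 1)
pair <- gen_tile_pair(tex, c(69, 66), tile_size = 1024)
estimate_offset(pair$tileA, pair$tileB, max_offset = 256)
#> offset dx=69 dy=66 (peak 9.128e+05)

# -- CORE: truth + three erroneous tracings (jitter, truncation, graft)
truth <- gen_skeleton(3, volume = c(20000, 20000, 20000), step = 160,
                      seed = 1, total_length = 20000)
mk <- function(id, ...) { s <- perturb_skeleton(truth, ...); s$id <- id; s }
tracings <- list(
  mk(1L, jitter_sd = 20, seed = 101),
  mk(2L, jitter_sd = 20, truncate_fraction = 0.2, seed = 102),
  mk(3L, jitter_sd = 20, graft_length = 5000, graft_count = 1, seed = 103))

res <- core_iterate(tracings, radius = 500, min_agreement = 2,
                    resolver = oracle_resolver(truth))
res
#> CORE result: 3 rounds, 302 consolidated nodes, 0 open mismatch(es)

reconstruction_metrics(res$skeleton, truth, tolerance = 100)
#> recall 0.9983, precision 0.9925, relative length error 0.0137 (tolerance 100 nm)
```

The registration recovers the displacement exactly; the consolidated
skeleton covers 99.8 % of the true arbor length and is 99.3 % free of
spurious length at 100 nm tolerance, with the 5 µm graft removed and the
truncated 20 % restored from the agreeing tracings.

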