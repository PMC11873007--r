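# lazyresample

Lazy composition and resampling of spatial preprocessing pipelines for
N-dimensional (2D/3D, channel-first) medical images in R.

## Why

Preprocessing pipelines for volumetric images — resample to a target
spacing, flip, rotate by quarter turns, zoom, rotate freely, crop —
traditionally execute one resample per transform. Every resample
interpolates; every interpolation blurs image detail and, for integer
segmentation labels under nearest-neighbour sampling, erodes label
boundaries. Crops and translations additionally destroy data outside the
viewport, which a later transform may still need.

`lazyresample` defers execution. Each spatial transform appends a
*pending operation* — an `(N+1)×(N+1)` homogeneous matrix in the pull
convention (output voxel coordinates ↦ input voxel coordinates, about
the image centre) plus interpolation/padding metadata — to the image.
Pipeline order composes by matrix product,

    M = M_1 · M_2 · … · M_k,

and a compiled pipeline executes all compatible pending operations as a
**single** resample, only where one is required. A universal resampler
picks the cheapest correct executor for each composed matrix: a
bit-exact array manipulation when the matrix is a signed permutation
with integer translation, otherwise one linear or nearest resample. So a
sequence like *rotate 45° → zoom 1.25 → rotate 22° → rotate −22° →
zoom 0.8 → rotate −45°* composes to the identity and costs nothing at
all, where a traditional pipeline pays six lossy resamples.

Applied transforms are recorded in an invertible trace, so labels can be
passed forward through an augmentation pipeline and back through its
inverse with as few resamples on the way back as the forward pass used.

## Worked example

```r
library(lazyresample)

# seeded 64^3 phantom: textured image + 3 small ellipsoidal label classes
ph <- phantom_volume(phantom_spec(seed = 3, spacing = c(1.1, 1.1, 1.1)))

# spacing -> random flip -> random rot90 -> random zoom -> random rotate
specs <- whole_volume_pipeline()

lazy <- execute_pipeline(compile_pipeline(specs, lazy_default = TRUE,
                                          master_seed = 7), ph$image)
trad <- execute_pipeline(compile_pipeline(specs, lazy_default = FALSE,
                                          master_seed = 7), ph$image)
count_events(lazy)$interpolations
#> [1] 1
count_events(trad)$interpolations
#> [1] 3

# round-trip the labels (nearest-neighbour) through pipeline + inverse
lab  <- execute_pipeline(compile_pipeline(specs, TRUE, master_seed = 7),
                         ph$labels)
back <- execute_pipeline(invert_pipeline(lab$trace), lab)
dice_report(ph$labels$data, back$data)$per_class
#>         1         2         3
#> 0.9922835 0.9950180 0.9946946
```

Identical random draws in both modes (streams are keyed by master seed
and pipeline position, never by execution mode) mean the only difference
between `lazy` and `trad` is resampling: one interpolation pass instead
of three forward, two instead of six over a full round trip — and
measurably higher round-trip Dice and lower entropy loss.

The checkerboard demonstration (`run_moire()`) scales boards by 6/5 then
5/6: lazily the round trip is bit-exact; traditionally it leaves moire
artifacts, hundreds of new intermediate intensity values and a large
histogram divergence.

## Command line

A thin launcher is installed at `inst/cli/lazyresample`:

```sh
Rscript inst/cli/lazyresample fixtures generate --out fx --n 3 --seed 1
Rscript inst/cli/lazyresample run forward   --config cfg.yaml --seed 1 --out out/
Rscript inst/cli/lazyresample run roundtrip --config cfg.yaml --seed 1 --out out/
Rscript inst/cli/lazyresample run moire     --out out/
```

Configs are YAML or JSON: an ordered `pipeline` list (`{name: rotate,
angles_deg: [10, 0, 5], lazy: true, mode: linear, padding: zeros}`,
angles in degrees in configs), plus `shape`, `spacing`, `n_samples`,
`master_seed`. Reports are written as CSV and JSON; the moire command
also writes PNG image grids.

## Layout

- `R/` — data model (`meta_image`, `pending_op`, `trace_record`),
  transforms (`lz_*`), pipeline compiler, universal resampler, metrics,
  synthetic data, experiments, CLI.
- `tests/testthat/` — unit, property and end-to-end suites.
- `vignettes/lazy-resampling.Rmd` — the methods vignette: conventions,
  dispatch rules, numerical choices, generator design, limitations.
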