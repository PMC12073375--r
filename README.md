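# fibremesh

Image-based morphometry for electrospun fiber meshes, written for
materials scientists characterizing fibrous scaffolds (e.g. regenerated
bacterial cellulose) from scanning electron micrographs.

From a calibrated grayscale micrograph the package measures:

* **Fiber diameter distribution** — binarization (Otsu or fixed
  threshold), topology-preserving skeletonization to 1-px centerlines,
  and local diameters `d = 2·EDT` from the Euclidean distance transform
  at every skeleton pixel; mean, population SD, median and a skewness
  flag (`mean > median`).
* **Pore size distribution** — connected components of the mask
  complement, each summarized by its equivalent diameter
  `d_eq = 2·sqrt(area/π)` and binned into size classes by void-area
  share; border-touching pores excluded but accounted.
* **Total fiber length and surface area** — the skeleton's 8-connected
  chain length (steps weighted 1 / √2) converted to µm, multiplied by
  the cylinder lateral area per unit length `A* = π·d`, and normalized
  by the imaged area so samples compare as ratios.
* **Absorption capacity** — `AC(%) = (W_h − W_d)/W_d × 100` over soak
  time series, with an equilibrium-time criterion.
* **Molar-mass averages** — `Mn`, `Mw`, `Mz` and the polydispersity
  index `Mw/Mn` from a mass/abundance table or raw mass samples.

Every estimator is validated against a built-in synthetic mesh
generator (`generate_mesh()`) that renders fibers as constant-width
strokes with exact ground truth: per-fiber centerlines and diameters,
binary masks, and the analytic surface area `Σ π·d_f·L_f`.

## Worked example

```r
library(fibremesh)

# a synthetic SEM-like micrograph: 1024 px at 0.05 um/px, 60 chords,
# lognormal diameters (median 0.48 um, sigma_log 0.586)
sim <- generate_mesh(mesh_spec(1024, 1024, n_fibers = 60, seed = 42))
sim$truth
#> <mesh_truth> 60 fibers, total length 2628.0 um, area fraction 0.447
#>   analytic surface area 4946.9 um^2 (cylindrical model)

bundle <- run_measure(sim, run_config(um_per_px = 0.05), sample_id = "gvl")
bundle
#> <metrics_bundle> 'gvl'
#> <fiber_stats> n = 27484: mean 0.692 +/- 0.439 um, median 0.600 um (positively skewed)
#> <surface_area_estimate> [per_pixel] L = 2190.1 um, A = 4816.9 um^2, normalized 1.8375
#>   pores: 526 included, 24 border-excluded
```

The bundle reports 27 484 diameter measurement pixels with a positively
skewed distribution (mean 0.69 µm above the 0.60 µm median — a minority
of thick fibers), an estimated 2 190 µm of fiber centerline in the
51.2 × 51.2 µm field, and a fiber surface area of 1.84× the imaged area
(`normalized`). On this dense overlapping mesh the mask-based length
underestimates the per-fiber truth (2 628 µm) because crossing fibers
share pixels; recovery is exact to a few percent on non-overlapping
validation meshes (`placement = "segment", allow_overlap = FALSE`).

```r
bundle$pore_table
#> <pore_table> 526 pores included, 24 border-touching excluded
#>  lower_um upper_um void_area_fraction count
#>       0.0      0.2       0.0005214932   151
#>       ...
#>       1.0      Inf       0.9665585400   238

# absorption: a mesh soaking up to ~40x its dry weight
s <- absorption_series(data.frame(
  time_h = c(0.5, 1, 2, 4, 8, 24),
  W_h_g  = c(9.2, 16.4, 25.9, 35.1, 40.3, 40.8),
  W_d_g  = 1))
s
#> <absorption_series> 6 time points, final AC 3980.0%
#>   equilibrium (rel. change < 2.0%) from t = 8 h

# molar-mass averages of a lognormal distribution with Mw/Mn = 1.46
set.seed(1)
mwd_averages(exp(rnorm(1e5, log(1.8e6), sqrt(log(1.46)))))
#> <mwd_averages> Mn 2.174e+06, Mw 3.174e+06, Mz 4.598e+06 g/mol; PDI 1.46
```

Two samples are compared with `run_compare(bundle_a, bundle_b)`, which
reports the normalized surface-area ratio and side-by-side pore class
fractions. A thin command-line wrapper with subcommands
`simulate | measure | pores | surface | compare | absorb | mwd` is
installed at `inst/cli/fibremesh` (exit codes: 2 validation, 3 I/O,
4 computation).

## Package layout

* `R/mesh-spec.R`, `R/generate-mesh.R` — synthetic mesh generator and
  ground truth
* `R/imaging-io.R` — image I/O, scale calibration, metric persistence
* `R/segmentation.R`, `src/thinning.cpp` — thresholding, thinning
  (Zhang–Suen + minimality pass), spur pruning, chain length
* `R/morphometry.R` — diameters, pores, surface area, comparisons
* `R/assay.R` — absorption capacity, molar-mass averages
* `R/pipeline.R` — end-to-end orchestration and reports
* `vignettes/fibremesh-methods.Rmd` — the models, estimator choices,
  bias analysis and validation scales
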