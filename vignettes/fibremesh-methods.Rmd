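---
title: "Fiber-mesh morphometry: models, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber-mesh morphometry: models, estimators and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Electrospun meshes of regenerated cellulose (and fibrous scaffolds
generally) are characterized from scanning electron micrographs by a
small set of morphometrics: the distribution of fiber diameters, the
distribution of pore sizes in the fiber network, the total visible fiber
length, and the total fiber surface area exposed per unit of imaged
area. fibremesh implements this chain as a reproducible pipeline and
validates every stage against a synthetic mesh generator with exact
ground truth.

The physical model is the **cylindrical fiber**: a fiber of diameter $d$
exposes a lateral surface of

$$A^{*} = \pi d$$

per unit axis length. The total surface area of a mesh image is then the
centerline length multiplied by $A^{*}$, and two meshes are compared by
their surface areas normalized by the imaged physical area. Water uptake
is summarized by the absorption capacity

$$AC(\%) = \frac{W_h - W_d}{W_d} \times 100,$$

the percent weight gain of a dry sample after soaking, and polymer
feedstock is summarized by the molar-mass averages
$M_n = \sum N_i M_i / \sum N_i$,
$M_w = \sum N_i M_i^2 / \sum N_i M_i$,
$M_z = \sum N_i M_i^3 / \sum N_i M_i^2$ and the polydispersity index
$M_w/M_n$.

# Pipeline stages and the choices behind them

## Calibration

The scale is either given directly in µm/px or derived from a scale bar
as `bar_label_um / bar_length_px`. Automatic bar detection is not
attempted: bar styles vary across instruments, and a manual pixel
measurement is unambiguous and auditable. Every reported length scales
linearly with the calibration and every area quadratically; this
equivariance is asserted end-to-end in the test suite.

## Binarization and cleanup

Fibers are bright on a dark background; a pixel is foreground when its
intensity reaches the threshold. The default threshold is Otsu's method
(no interactive tuning, deterministic); a fixed threshold is available
when strict cross-study reproducibility matters more than adaptivity. A
constant image has no foreground/background separation and is an error,
not an empty result. Cleanup removes connected components below
`min_object_px` (default 25 px, well below any plausible fiber fragment
at the default scale) and optionally applies morphological closing;
both default to conservative values because the synthetic noise model
(additive Gaussian, sd 0.05 on unit intensities) almost never flips a
pixel across an Otsu threshold that sits mid-way between the two modes.

## Skeletonization and length

Masks are thinned to one-pixel centerlines with Zhang–Suen thinning.
Two artifacts of that algorithm matter quantitatively and are corrected:

* **Diagonal ladders.** Zhang–Suen can leave two-pixel-wide diagonal
  staircases whose chain length reads as an axial staircase — up to
  +41 % on a 45° fiber. A sequential minimality pass deletes 8-simple,
  non-endpoint pixels (Yokoi connectivity number $N_c^8 = 1$) until the
  skeleton is minimal, collapsing ladders into clean diagonal runs while
  preserving topology and endpoints.
* **Spurs.** Short side branches sprouting at fiber edges are pruned
  when an endpoint reaches a junction within `prune_px` (default 5) px.
  Endpoint-to-endpoint paths are real fibers and are never pruned.

Length is the sum over undirected 8-neighbour steps with weights 1
(axial) and $\sqrt 2$ (diagonal), each step counted once; a diagonal
step is skipped when an axial pixel already joins its two ends, so an
L-shaped corner is counted once. A pixel-counting mode (weight 1
everywhere) is provided for compatibility with plain pixel-length
measurements. On digitized straight lines the $\{1, \sqrt 2\}$ chain
metric is exact at 0°, 45° and 90° and overestimates by up to ~7 % at
intermediate angles (~5.5 % averaged over orientations); capsule end
erosion partially offsets this, and the package's accuracy target for
total length on sparse meshes is 5 %.

## Local diameters

The local diameter at a skeleton pixel is twice its Euclidean distance
transform (EDT) value: $d = 2\,\mathrm{EDT} \cdot \text{µm/px}$. On an
axis-aligned ribbon of odd pixel width this reads one pixel high
(the nearest background pixel *center* sits half a pixel beyond the
boundary); on even widths it is exact and on diagonal orientations
slightly low. Averaged over random orientations and sub-pixel offsets
the net bias measured on clean synthetic capsules is below 0.1 px, which
is why the raw $2\,\mathrm{EDT}$ form is used rather than a half-pixel
"boundary" correction — the latter looks attractive on the odd-width
axial case but overcorrects everywhere else.

Two kinds of sample are flagged and excluded from the statistics (but
retained for surface-area integration, where their surface is real):
pixels within 2 px (Chebyshev) of a skeleton junction, where crossing
fibers inflate the EDT, and pixels whose distance to the image border is
within 1 px of their EDT, where the border clips the inscribed disc.

Statistics are the mean, the population standard deviation, the
linearly-interpolated median, and a fixed-width histogram (default
0.1 µm bins). The skewness flag is simply `mean > median`, the signature
of a minority of unusually thick fibers. `n` counts measurement pixels;
`per_fiber_diameters()` collapses to one median value per labelled fiber
for protocols that count each fiber once (conventionally at least 100).

## Pores

Pores are 8-connected components of the mask complement. Components
touching the image border are excluded from the distribution — their
true extent is unknown — but reported in `border_excluded_count`, and
the accounting identity
`included pore px + border pore px + fiber px = image px`
holds exactly. Each pore is summarized by its equivalent diameter
$d_{eq} = 2\sqrt{A/\pi}$ and classed into bins (default
0–0.2–0.4–0.6–0.8–1.0–∞ µm); class weights are shares of included void
*area*. "Void volume" in 2-D micrograph analysis is necessarily an area
fraction; the package uses the area meaning throughout.

## Surface area

Two integration rules are provided because published analyses rarely
state which was used:

* `mean_diameter`: total length × $\pi$ × mean included diameter;
* `per_pixel` (default): $\sum_{\text{steps}} \pi\, d(\text{step})\,
  \ell(\text{step})$ with the step diameter the mean of its two
  endpoint samples — robust when local diameter varies along fibers.

Both are normalized by the imaged physical area, and two meshes are
compared by the ratio of normalized estimates. For non-overlapping
cylinders there is an independent identity, used as a cross-check in the
tests: the per-pixel total area approximates $\pi$ × (fiber mask area),
because a cylinder's lateral surface is $\pi$ times its projected area.
Overlap breaks this identity in a known direction (the union mask
under-counts), which is why validation meshes are generated
non-overlapping.

## Absorption and molar-mass averages

The soak series applies the $AC$ formula per time point; times must be
strictly increasing with a single dry weight. Equilibrium is defined as
the first time point from which the relative change between consecutive
capacities stays below a tolerance (default 2 %) through the end of the
series — the criterion is configurable because published protocols say
only "until equilibrium". The molar-mass module accepts abundance
tables or raw per-molecule samples; the averages satisfy
$M_n \le M_w \le M_z$ (power-mean inequality) with equality only for a
monodisperse sample, and for lognormal mass distributions
$M_w/M_n = e^{\sigma^2}$, which the tests exploit: draws with
$\sigma^2 = \ln 1.46$ must recover PDI 1.46.

# The synthetic generator

`generate_mesh()` draws fibers as constant-width strokes along straight
(or gently bowed quadratic-Bézier) centerlines, freezes the exact
ground-truth masks, per-fiber centerlines, diameters and the analytic
total $\sum_f \pi d_f L_f$, and only then adds intensity noise. A pixel
belongs to a stroke when its center lies within $d/2$ of the centerline,
which makes the expected rasterized width equal to the true diameter
under random sub-pixel placement. Strokes are capsules (rounded caps):
blunt ends would send the medial axis into the end corners and corrupt
skeleton length at every fiber tip by roughly one radius.

Defaults emulate the statistics of a 4000×-magnification micrograph of
an electrospun cellulose mesh: 0.05 µm/px (a 10 µm scale bar spanning
200 px), lognormal diameters with median 0.48 µm and log-sd 0.586
(mean $0.48\,e^{0.586^2/2} = 0.57$ µm, SD ≈ 0.33 µm), fibers brighter
(0.8) than background (0.2), additive Gaussian noise sd 0.05. Fiber
placement has two modes:

* `chord` (default): border-to-border chords, matching the long
  through-going fibers seen in dense electrospun meshes; overlap
  allowed, union mask, per-fiber totals counted in full (projection
  convention — documented because overlap biases mask-based estimators
  low).
* `segment`: finite sticks with lengths drawn from `fiber_length_um`,
  kept inside the image, with optional rejection-sampled non-overlap
  (2 px clearance). Non-overlapping placement is what makes exact
  recovery testable; random sequential placement of long high-aspect
  sticks jams well below nominal coverage, so validation meshes use
  4–8 µm sticks, which place reliably at ~10 % coverage with hundreds
  of fibers.

What the generator deliberately does **not** emulate: SEM contrast
physics (charging, shading, depth of field), 3-D fiber stacking and
layer occlusion, beads and diameter variation along a fiber. Passing
recovery tests therefore demonstrates the correctness of the estimators
on the cylindrical-fiber model, not robustness to every real-world
imaging artifact.

# Numerical conventions

* Matrices are indexed `[row, col]`, origin top-left, pixel centers at
  integer coordinates; the image occupies `[0.5, H+0.5] × [0.5, W+0.5]`.
* Population (not sample) SD; median by linear interpolation (R type-7).
* Histogram bins are left-open, right-closed; pore class fractions are
  area shares over included pores and sum to 1.
* Empty inputs are results, not errors, wherever a measurement is
  defined (empty mask → empty skeleton, length 0); errors are typed
  (validation / I/O / computation) and the CLI maps them to exit codes
  2 / 3 / 4.
* All randomness flows through a single integer seed per mesh; equal
  spec + seed reproduces images and ground truth bit-for-bit, and the
  caller's RNG state is never disturbed.

# Validation scales and limitations

The test suite validates recovery on a 1024² px mesh of 80
non-overlapping fibers and the acceptance script on a 2048² px mesh of
250 fibers (0.05 µm/px, coverage ≈ 0.09, a few seconds each on one
core); these sizes give the diameter-mean estimator a sampling error
comfortably inside its 10 % target while keeping the suite quick.

Known limitations: crossing fibers are not separated into individual
tracked fibers (junction neighbourhoods are excluded from diameter
statistics instead); the length metric carries the intrinsic digital
chain bias described above; sub-pixel centerline fitting is out of
scope; pore analysis is strictly 2-D; and mask-based estimators on
*overlapping* meshes are biased low by construction — comparisons
between meshes of similar density remain meaningful because the bias
largely cancels in the ratio.
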