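#' Describe a fiber diameter distribution
#'
#' Diameters of electrospun fibers are typically positively skewed; a
#' lognormal law parameterized by its median and log-scale spread matches
#' the reported summary statistics of such meshes (a median near 0.5 um
#' with mean exceeding median).
#'
#' @param kind `"constant"` or `"lognormal"`.
#' @param median_um Median fiber diameter in micrometers (> 0). For the
#'   constant law this is the common diameter.
#' @param sigma_log Standard deviation of `log(d)` (>= 0); ignored for the
#'   constant law. For a lognormal, `mean = median * exp(sigma_log^2 / 2)`.
#' @return A `diameter_law` object.
#' @examples
#' diameter_law("lognormal", median_um = 0.48, sigma_log = 0.586)
#' @export
diameter_law <- function(kind = c("lognormal", "constant"),
                         median_um = 0.48, sigma_log = 0.586) {
  kind <- match.arg(kind)
  check_scalar(median_um, "median_um", positive = TRUE)
  check_scalar(sigma_log, "sigma_log", nonneg = TRUE)
  if (kind == "constant") sigma_log <- 0
  structure(list(kind = kind, median_um = median_um, sigma_log = sigma_log),
            class = "diameter_law")
}

#' Sample fiber diameters from a distribution law
#'
#' @param law A [diameter_law()].
#' @param n Number of diameters to draw (>= 1).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return Numeric vector of `n` diameters in micrometers, all > 0.
#' @examples
#' d <- sample_diameters(diameter_law("lognormal", 0.48, 0.586), 1e4, seed = 1)
#' median(d) # ~0.48
#' @export
sample_diameters <- function(law, n, seed) {
  if (!inherits(law, "diameter_law"))
    fm_stop_validation("'law' must be a diameter_law object")
  check_scalar(n, "n", positive = TRUE, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  with_seed(seed, draw_diameters(law, n))
}

# draw from the current RNG stream (used inside generate_mesh)
draw_diameters <- function(law, n) {
  switch(law$kind,
    constant = rep(law$median_um, n),
    lognormal = exp(rnorm(n, mean = log(law$median_um), sd = law$sigma_log)),
    fm_stop_validation(sprintf("unsupported diameter law kind '%s'", law$kind))
  )
}

#' Specify a synthetic fiber-mesh micrograph
#'
#' Defines the geometry, optics and randomness of a synthetic SEM-like
#' micrograph of overlapping (or non-overlapping) cylindrical fibers, the
#' input to [generate_mesh()]. Defaults emulate a 4000x-magnification
#' micrograph of an electrospun cellulose mesh: 0.05 um/px, lognormal
#' diameters with median 0.48 um and log-sd 0.586 (mean 0.57 um), long
#' through-going fibers.
#'
#' @param image_width_px,image_height_px Image size in pixels (> 0).
#' @param um_per_px Physical pixel size in micrometers per pixel (> 0).
#' @param n_fibers Number of fibers (>= 0).
#' @param law Fiber diameter distribution, a [diameter_law()].
#' @param placement `"chord"` draws fibers as border-to-border chords
#'   (through-going fibers, as in low-magnification micrographs of dense
#'   meshes); `"segment"` draws finite sticks of length drawn uniformly
#'   from `fiber_length_um`, kept fully inside the image, which permits
#'   non-overlapping meshes.
#' @param fiber_length_um Length range `c(min, max)` in micrometers for
#'   `placement = "segment"`.
#' @param curvature Maximum relative sag of a fiber (0 = straight chords;
#'   0.1 bows the midpoint by up to 10% of the chord length).
#' @param allow_overlap If `FALSE`, fibers are placed by rejection sampling
#'   so their strokes (padded by `overlap_margin_px`) are pairwise disjoint.
#' @param overlap_margin_px Clearance in pixels enforced between fibers
#'   when `allow_overlap = FALSE`.
#' @param fg_intensity,bg_intensity Fiber and background intensities on
#'   `[0, 1]`; fibers must be brighter than background.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   applied after the ground-truth masks are frozen.
#' @param scale_bar Optional `list(length_um =, thickness_px =)`: a bright
#'   bar of known physical length drawn in a reserved bottom margin that
#'   fibers never enter, for calibration exercises.
#' @param seed Integer seed; identical spec + seed reproduces the mesh
#'   bit-for-bit.
#' @return A validated `mesh_spec` object.
#' @examples
#' spec <- mesh_spec(512, 512, n_fibers = 12, seed = 7)
#' @export
mesh_spec <- function(image_width_px = 1024, image_height_px = 1024,
                      um_per_px = 0.05, n_fibers = 60,
                      law = diameter_law("lognormal", 0.48, 0.586),
                      placement = c("chord", "segment"),
                      fiber_length_um = c(10, 20),
                      curvature = 0,
                      allow_overlap = TRUE,
                      overlap_margin_px = 2,
                      fg_intensity = 0.8, bg_intensity = 0.2,
                      noise_sd = 0.05,
                      scale_bar = NULL,
                      seed = 1L) {
  spec <- structure(list(
    image_width_px = image_width_px, image_height_px = image_height_px,
    um_per_px = um_per_px, n_fibers = n_fibers, law = law,
    placement = match.arg(placement), fiber_length_um = fiber_length_um,
    curvature = curvature, allow_overlap = allow_overlap,
    overlap_margin_px = overlap_margin_px,
    fg_intensity = fg_intensity, bg_intensity = bg_intensity,
    noise_sd = noise_sd, scale_bar = scale_bar, seed = as.integer(seed)
  ), class = "mesh_spec")
  validate_mesh_spec(spec)
}

validate_mesh_spec <- function(spec) {
  check_scalar(spec$image_width_px, "image_width_px", positive = TRUE, integerish = TRUE)
  check_scalar(spec$image_height_px, "image_height_px", positive = TRUE, integerish = TRUE)
  check_scalar(spec$um_per_px, "um_per_px", positive = TRUE)
  check_scalar(spec$n_fibers, "n_fibers", nonneg = TRUE, integerish = TRUE)
  if (!inherits(spec$law, "diameter_law"))
    fm_stop_validation("'law' must be a diameter_law object")
  if (spec$law$median_um / spec$um_per_px < 2)
    fm_stop_validation(sprintf(
      "median diameter is %.2f px at this scale; must be >= 2 px for a well-defined skeleton",
      spec$law$median_um / spec$um_per_px))
  check_scalar(spec$curvature, "curvature", nonneg = TRUE)
  check_scalar(spec$fg_intensity, "fg_intensity", nonneg = TRUE)
  check_scalar(spec$bg_intensity, "bg_intensity", nonneg = TRUE)
  if (spec$fg_intensity > 1 || spec$bg_intensity > 1)
    fm_stop_validation("intensities must lie in [0, 1]")
  if (spec$fg_intensity <= spec$bg_intensity)
    fm_stop_validation("'fg_intensity' must exceed 'bg_intensity'")
  check_scalar(spec$noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(spec$overlap_margin_px, "overlap_margin_px", nonneg = TRUE)
  if (spec$placement == "segment") {
    if (!is.numeric(spec$fiber_length_um) || length(spec$fiber_length_um) != 2L ||
        any(spec$fiber_length_um <= 0) || diff(spec$fiber_length_um) < 0)
      fm_stop_validation("'fiber_length_um' must be c(min, max) with 0 < min <= max")
  }
  if (!is.null(spec$scale_bar)) {
    if (!is.list(spec$scale_bar) ||
        is.null(spec$scale_bar$length_um) || is.null(spec$scale_bar$thickness_px))
      fm_stop_validation("'scale_bar' must be list(length_um =, thickness_px =)")
    check_scalar(spec$scale_bar$length_um, "scale_bar$length_um", positive = TRUE)
    check_scalar(spec$scale_bar$thickness_px, "scale_bar$thickness_px",
                 positive = TRUE, integerish = TRUE)
  }
  check_scalar(spec$seed, "seed", integerish = TRUE)
  spec
}

#' @export
print.mesh_spec <- function(x, ...) {
  cat(sprintf("<mesh_spec> %d x %d px @ %.4g um/px, %d fibers (%s)\n",
              x$image_width_px, x$image_height_px, x$um_per_px,
              x$n_fibers, x$placement))
  cat(sprintf("  diameters: %s median %.3g um, sigma_log %.3g; seed %d\n",
              x$law$kind, x$law$median_um, x$law$sigma_log, x$seed))
  invisible(x)
}
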