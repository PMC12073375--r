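# End-to-end measurement pipeline: calibrate -> binarize -> clean ->
# skeletonize -> diameters -> stats / pores / surface area.

#' Configuration for the measurement pipeline
#'
#' Collects and validates every stage parameter up front; the validated
#' configuration is persisted verbatim alongside any outputs so a run can
#' be reproduced exactly.
#'
#' @param um_per_px Physical scale (um/pixel); alternatively give
#'   `bar_length_px` + `bar_label_um` to derive it from a scale bar.
#' @param bar_length_px,bar_label_um Scale-bar measurement (both > 0).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold for `threshold_method = "fixed"`.
#' @param min_object_px,closing_radius_px Mask cleanup parameters.
#' @param prune_px Skeleton spur-pruning length (px).
#' @param junction_radius_px Diameter-sample exclusion radius around
#'   junctions (px).
#' @param bins_um Pore equivalent-diameter class boundaries (um).
#' @param fiber_bin_width_um Fiber-diameter histogram bin width (um).
#' @param mode Surface-area integration: `"per_pixel"` or
#'   `"mean_diameter"`.
#' @param min_n Diameter sample-size floor before a low-n warning.
#' @param length_mode Skeleton length metric, `"weighted"` (1 / sqrt(2)
#'   steps) or `"pixel_count"`.
#' @return A validated `run_config` object.
#' @export
run_config <- function(um_per_px = NULL,
                       bar_length_px = NULL, bar_label_um = NULL,
                       threshold_method = c("otsu", "fixed"),
                       fixed_threshold = NULL,
                       min_object_px = 25L, closing_radius_px = 0L,
                       prune_px = 5L, junction_radius_px = 2L,
                       bins_um = c(0, 0.2, 0.4, 0.6, 0.8, 1.0, Inf),
                       fiber_bin_width_um = 0.1,
                       mode = c("per_pixel", "mean_diameter"),
                       min_n = 100L,
                       length_mode = c("weighted", "pixel_count")) {
  cal <- if (!is.null(um_per_px)) calibration(um_per_px)
         else if (!is.null(bar_length_px) && !is.null(bar_label_um))
           calibrate(bar_length_px, bar_label_um)
         else fm_stop_validation(
           "supply either 'um_per_px' or both 'bar_length_px' and 'bar_label_um'")
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed")
    check_scalar(fixed_threshold, "fixed_threshold", nonneg = TRUE)
  check_scalar(min_object_px, "min_object_px", nonneg = TRUE, integerish = TRUE)
  check_scalar(closing_radius_px, "closing_radius_px", nonneg = TRUE,
               integerish = TRUE)
  check_scalar(prune_px, "prune_px", nonneg = TRUE, integerish = TRUE)
  check_scalar(junction_radius_px, "junction_radius_px", nonneg = TRUE,
               integerish = TRUE)
  check_scalar(fiber_bin_width_um, "fiber_bin_width_um", positive = TRUE)
  check_scalar(min_n, "min_n", positive = TRUE, integerish = TRUE)
  structure(list(
    calibration = cal,
    threshold_method = threshold_method, fixed_threshold = fixed_threshold,
    min_object_px = as.integer(min_object_px),
    closing_radius_px = as.integer(closing_radius_px),
    prune_px = as.integer(prune_px),
    junction_radius_px = as.integer(junction_radius_px),
    bins_um = bins_um, fiber_bin_width_um = fiber_bin_width_um,
    mode = match.arg(mode), min_n = as.integer(min_n),
    length_mode = match.arg(length_mode)
  ), class = "run_config")
}

with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    if (inherits(e, "fm_error") && is.null(attr(e, "fm_stage"))) {
      e$message <- sprintf("[stage %s] %s", stage, conditionMessage(e))
      attr(e, "fm_stage") <- stage
      stop(e)
    }
  })
}

#' Measure a fiber-mesh micrograph end-to-end
#'
#' Runs the full morphometry chain on one image: binarization, mask
#' cleanup, skeletonization, distance-transform diameters, diameter
#' statistics, pore size distribution and total fiber surface area. The
#' run is deterministic for a fixed image and configuration. When
#' `out_dir` is given, metric CSV/JSON files and the verbatim
#' configuration are written there (atomically: temp file then rename).
#'
#' @param image An image file path (TIFF/PNG), a numeric matrix in
#'   `[0, 1]`, or a `mesh_sim` from [generate_mesh()].
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param sample_id Identifier used in output records.
#' @return A `metrics_bundle`: `fiber_stats`, `pore_table`,
#'   `surface_area`, `skeleton`, `diameters`, `mask`, `config`,
#'   `sample_id`.
#' @export
run_measure <- function(image, config, out_dir = NULL, sample_id = "sample") {
  if (!inherits(config, "run_config"))
    fm_stop_validation("'config' must be a run_config")
  img <- with_stage("load_image", {
    if (inherits(image, "mesh_sim")) image$image
    else if (is.matrix(image) && is.numeric(image)) image
    else load_image(image)
  })
  cal <- config$calibration
  mask <- with_stage("binarize",
    binarize(img, config$threshold_method, config$fixed_threshold))
  mask <- with_stage("clean_mask",
    clean_mask(mask, config$min_object_px, config$closing_radius_px))
  skel <- with_stage("skeletonize",
    skeletonize_mask(mask, config$prune_px, cal))
  dia <- with_stage("local_diameters",
    local_diameters(mask, skel, cal, config$junction_radius_px))
  stats <- with_stage("fiber_stats", {
    if (nrow(dia) == 0L || all(dia$excluded))
      fm_stop_computation("no usable diameter samples in this image")
    fiber_stats(dia, config$min_n, config$fiber_bin_width_um)
  })
  pores <- with_stage("pore_distribution",
    pore_distribution(mask, cal, config$bins_um))
  surf <- with_stage("total_surface_area",
    total_surface_area(skel, dia, cal, config$mode))
  bundle <- structure(list(
    sample_id = sample_id,
    fiber_stats = stats, pore_table = pores, surface_area = surf,
    skeleton = skel, diameters = dia, mask = mask,
    total_length_um = total_length(skel, cal, config$length_mode),
    config = config
  ), class = "metrics_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

bundle_record <- function(b) {
  s <- b$fiber_stats
  data.frame(
    sample_id = b$sample_id, n = s$n,
    mean_um = s$mean_um, sd_um = s$sd_um, median_um = s$median_um,
    skew_flag = s$positively_skewed,
    total_length_um = b$total_length_um,
    A_star_um = b$surface_area$A_star_um,
    total_area_um2 = b$surface_area$total_area_um2,
    normalized_area = b$surface_area$normalized,
    n_pores = nrow(b$pore_table$pores),
    border_excluded_pores = b$pore_table$border_excluded_count,
    um_per_px = b$config$calibration$um_per_px
  )
}

write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_atomic <- function(writer, final) {
    tmp <- paste0(final, ".tmp")
    writer(tmp)
    if (file.exists(paste0(tmp, ".json")))
      file.rename(paste0(tmp, ".json"), paste0(final, ".json"))
    file.rename(tmp, final)
  }
  id <- bundle$sample_id
  write_atomic(function(p) write_metrics(bundle_record(bundle), p),
               file.path(out_dir, paste0(id, "_fiber_stats.csv")))
  write_atomic(function(p) write_metrics(bundle$pore_table$classes, p),
               file.path(out_dir, paste0(id, "_pore_classes.csv")))
  if (nrow(bundle$pore_table$pores))
    write_atomic(function(p) write_metrics(bundle$pore_table$pores, p),
                 file.path(out_dir, paste0(id, "_pores.csv")))
  cfg <- bundle$config
  cfg$calibration <- unclass(cfg$calibration)
  write_atomic(function(p) jsonlite::write_json(unclass(cfg), p,
                                                auto_unbox = TRUE, digits = NA,
                                                null = "null"),
               file.path(out_dir, paste0(id, "_config.json")))
  invisible(out_dir)
}

#' @export
print.metrics_bundle <- function(x, ...) {
  cat(sprintf("<metrics_bundle> '%s'\n", x$sample_id))
  print(x$fiber_stats)
  print(x$surface_area)
  cat(sprintf("  pores: %d included, %d border-excluded\n",
              nrow(x$pore_table$pores), x$pore_table$border_excluded_count))
  invisible(x)
}

#' Compare two measured meshes
#'
#' Side-by-side report of two [run_measure()] bundles: the normalized
#' surface-area ratio (A over B) and the per-class pore void-area
#' fractions and diameter summaries of both samples. Bundles measured at
#' different calibrations cannot be compared.
#'
#' @param bundle_a,bundle_b `metrics_bundle` objects.
#' @return A `mesh_comparison`: `surface_area_ratio`, `fiber_summary`
#'   (one row per sample), `pore_classes` (fractions for both samples).
#' @export
run_compare <- function(bundle_a, bundle_b) {
  if (!inherits(bundle_a, "metrics_bundle") ||
      !inherits(bundle_b, "metrics_bundle"))
    fm_stop_validation("both arguments must be metrics_bundle objects")
  ua <- bundle_a$config$calibration$um_per_px
  ub <- bundle_b$config$calibration$um_per_px
  if (!isTRUE(all.equal(ua, ub)))
    fm_stop_validation(sprintf(
      "unit mismatch: bundles calibrated at %g and %g um/px cannot be compared",
      ua, ub))
  ratio <- compare_surface_areas(bundle_a$surface_area, bundle_b$surface_area)
  ids <- c(bundle_a$sample_id, bundle_b$sample_id)
  if (ids[1] == ids[2]) ids <- paste0(ids, c("_a", "_b"))
  pc <- bundle_a$pore_table$classes[, c("lower_um", "upper_um")]
  pc[[paste0("frac_", ids[1])]] <- bundle_a$pore_table$classes$void_area_fraction
  pc[[paste0("frac_", ids[2])]] <- bundle_b$pore_table$classes$void_area_fraction
  structure(list(
    surface_area_ratio = ratio,
    fiber_summary = rbind(bundle_record(bundle_a), bundle_record(bundle_b)),
    pore_classes = pc
  ), class = "mesh_comparison")
}

#' @export
print.mesh_comparison <- function(x, ...) {
  cat(sprintf("<mesh_comparison> normalized surface-area ratio A/B = %.3f\n",
              x$surface_area_ratio))
  print(x$fiber_summary[, c("sample_id", "n", "mean_um", "median_um",
                            "normalized_area")], row.names = FALSE)
  invisible(x)
}
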