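#' Pixel-to-micron calibration
#'
#' The physical scale of a micrograph is either supplied directly
#' (micrometers per pixel) or derived from an embedded scale bar whose
#' pixel length was measured by the user: `um_per_px = bar_label_um /
#' bar_length_px`. Automatic scale-bar detection is deliberately not
#' attempted; manual bar measurement is unambiguous.
#'
#' @param bar_length_px Measured bar length in pixels (> 0).
#' @param bar_label_um Physical bar length printed on the micrograph (> 0).
#' @return A `calibration` object with fields `um_per_px` and `source`.
#' @examples
#' calibrate(200, 10)  # 0.05 um/px
#' @export
calibrate <- function(bar_length_px, bar_label_um) {
  check_scalar(bar_length_px, "bar_length_px", positive = TRUE)
  check_scalar(bar_label_um, "bar_label_um", positive = TRUE)
  structure(list(um_per_px = bar_label_um / bar_length_px,
                 source = "scale_bar"),
            class = "calibration")
}

#' @param um_per_px Known physical pixel size in micrometers per pixel.
#' @rdname calibrate
#' @export
calibration <- function(um_per_px) {
  check_scalar(um_per_px, "um_per_px", positive = TRUE)
  structure(list(um_per_px = um_per_px, source = "explicit"),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.6g um/px (%s)\n", x$um_per_px, x$source))
  invisible(x)
}

as_calibration <- function(x) {
  if (inherits(x, "calibration")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(calibration(x))
  fm_stop_validation("expected a calibration object or a single um/px value")
}

#' Load a grayscale micrograph
#'
#' Reads an 8- or 16-bit TIFF or PNG, averaging RGB channels if present
#' (SEM images are usually grayscale stored in an RGB container), and
#' returns intensities normalized to `[0, 1]` as a `[row, col]` matrix.
#'
#' @param path Image file path (`.tif`, `.tiff` or `.png`).
#' @return Numeric matrix in `[0, 1]` with attribute `path`.
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    fm_stop_io(sprintf("image file does not exist: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      tif = , tiff = tiff::readTIFF(path),
      png = png::readPNG(path),
      fm_stop_io(sprintf("unsupported image format '.%s' for '%s' (use TIFF or PNG)",
                         ext, path))
    ),
    error = function(e) {
      if (inherits(e, "fm_error")) stop(e)
      fm_stop_io(sprintf("failed to read '%s': %s", path, conditionMessage(e)))
    })
  if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
  if (!is.matrix(img))
    fm_stop_io(sprintf("'%s' did not decode to a 2-D image", path))
  structure(img, path = path)
}

#' Save a grayscale image
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output path; format chosen by extension (TIFF or PNG).
#' @param bits Bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, bits = 16L) {
  if (!is.matrix(img) || !is.numeric(img))
    fm_stop_validation("'img' must be a numeric matrix")
  if (!bits %in% c(8L, 16L)) fm_stop_validation("'bits' must be 8 or 16")
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
      tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits)),
      png = png::writePNG(img, path),
      fm_stop_io(sprintf("unsupported image format '.%s' for '%s'", ext, path)))
    TRUE
  }, error = function(e) {
    if (inherits(e, "fm_error")) stop(e)
    fm_stop_io(sprintf("failed to write '%s': %s", path, conditionMessage(e)))
  })
  invisible(path)
}

#' Write and re-read metric records
#'
#' Records (any data frame of per-sample metrics) are written as CSV with
#' numbers serialized at full double precision (`%.17g`, well beyond the
#' 9-significant-digit floor needed for reproducible re-analysis), plus an
#' optional JSON mirror carrying exact doubles.
#'
#' @param records A data frame.
#' @param path Output CSV path.
#' @param json_mirror If `TRUE`, also write `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, path, json_mirror = TRUE) {
  if (!is.data.frame(records))
    fm_stop_validation("'records' must be a data.frame")
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e)
    fm_stop_io(sprintf("failed to write '%s': %s", path, conditionMessage(e))))
  if (json_mirror)
    jsonlite::write_json(records, paste0(path, ".json"),
                         auto_unbox = FALSE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) fm_stop_io(sprintf("no such file: '%s'", path))
  read.csv(path, stringsAsFactors = FALSE)
}
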