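# Synthetic mesh rendering.
#
# Coordinate convention (shared by all modules): matrices are indexed
# [row, col], origin at the top-left, pixel centers at integer coordinates,
# so the image occupies the box [0.5, H + 0.5] x [0.5, W + 0.5]. A pixel
# belongs to a fiber stroke when its center lies within d/2 of the
# centerline, which makes the expected rasterized width equal to the true
# diameter for random sub-pixel placements.

# Rasterize one straight segment of half-width r into linear pixel indices.
rasterize_segment <- function(p0, p1, r, H, W, row_max = H) {
  dr <- p1[1] - p0[1]; dc <- p1[2] - p0[2]
  if (dr == 0 && dc == 0) return(integer(0))
  if (abs(dc) >= abs(dr)) {
    m <- dr / dc
    v <- r * sqrt(1 + m^2)
    cols <- seq.int(max(1L, ceiling(min(p0[2], p1[2]))),
                    min(W, floor(max(p0[2], p1[2]))))
    if (length(cols) == 0L) return(integer(0))
    ctr <- p0[1] + (cols - p0[2]) * m
    lo <- pmax(1, ceiling(ctr - v)); hi <- pmin(row_max, floor(ctr + v))
    n <- pmax(0, hi - lo + 1)
    keep <- n > 0
    if (!any(keep)) return(integer(0))
    rows <- sequence(n[keep], from = lo[keep])
    cc <- rep.int(cols[keep], n[keep])
    as.integer(rows + (cc - 1) * H)
  } else {
    m <- dc / dr
    v <- r * sqrt(1 + m^2)
    rows <- seq.int(max(1L, ceiling(min(p0[1], p1[1]))),
                    min(row_max, floor(max(p0[1], p1[1]))))
    if (length(rows) == 0L) return(integer(0))
    ctr <- p0[2] + (rows - p0[1]) * m
    lo <- pmax(1, ceiling(ctr - v)); hi <- pmin(W, floor(ctr + v))
    n <- pmax(0, hi - lo + 1)
    keep <- n > 0
    if (!any(keep)) return(integer(0))
    cc <- sequence(n[keep], from = lo[keep])
    rr <- rep.int(rows[keep], n[keep])
    as.integer(rr + (cc - 1) * H)
  }
}

# Disk stamp centered at a (possibly fractional) point; used at polyline
# joints so consecutive segment bands leave no wedge gaps.
rasterize_disk <- function(p, r, H, W, row_max = H) {
  rows <- seq.int(max(1L, ceiling(p[1] - r)), min(row_max, floor(p[1] + r)))
  cols <- seq.int(max(1L, ceiling(p[2] - r)), min(W, floor(p[2] + r)))
  if (length(rows) == 0L || length(cols) == 0L) return(integer(0))
  g <- expand.grid(r = rows, c = cols)
  keep <- (g$r - p[1])^2 + (g$c - p[2])^2 <= r^2
  as.integer(g$r[keep] + (g$c[keep] - 1) * H)
}

# Strokes are capsules: segment bands plus disks at every vertex, so ends
# are rounded. Blunt (butt) ends would send the medial axis into the end
# corners, corrupting skeleton length at every fiber tip.
rasterize_polyline <- function(poly, r, H, W, row_max = H) {
  n <- nrow(poly)
  idx <- vector("list", n + 1L)
  for (i in seq_len(n - 1))
    idx[[i]] <- rasterize_segment(poly[i, ], poly[i + 1, ], r, H, W, row_max)
  for (i in seq_len(n))
    idx[[n + 1L]] <- c(idx[[n + 1L]], rasterize_disk(poly[i, ], r, H, W, row_max))
  unique(unlist(idx))
}

polyline_length_px <- function(poly) {
  if (nrow(poly) < 2) return(0)
  sum(sqrt(rowSums((poly[-1, , drop = FALSE] -
                    poly[-nrow(poly), , drop = FALSE])^2)))
}

# point on the boundary box [0.5, H+0.5] x [0.5, W+0.5] at perimeter
# parameter t in [0, 1)
perimeter_point <- function(t, H, W) {
  P <- 2 * (H + W)
  s <- t * P
  if (s < W) c(0.5, 0.5 + s)
  else if (s < W + H) c(0.5 + (s - W), W + 0.5)
  else if (s < 2 * W + H) c(H + 0.5, W + 0.5 - (s - W - H))
  else c(H + 0.5 - (s - 2 * W - H), 0.5)
}

# quadratic Bezier through-sampled polyline
bezier_polyline <- function(p0, ctrl, p1, k = 48) {
  t <- seq(0, 1, length.out = k + 1)
  rows <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * ctrl[1] + t^2 * p1[1]
  cols <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * ctrl[2] + t^2 * p1[2]
  cbind(rows, cols)
}

propose_polyline <- function(spec, row_max, W) {
  H <- row_max
  if (spec$placement == "chord") {
    repeat {
      p0 <- perimeter_point(runif(1), H, W)
      p1 <- perimeter_point(runif(1), H, W)
      L <- sqrt(sum((p1 - p0)^2))
      if (L >= 0.3 * min(H, W)) break
    }
    if (spec$curvature > 0) {
      mid <- (p0 + p1) / 2
      u <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
      nrm <- c(-u[2], u[1])
      sag <- spec$curvature * sqrt(sum((p1 - p0)^2)) * runif(1, -1, 1)
      ctrl <- mid + 2 * sag * nrm  # Bezier midpoint offset is half the control offset
      poly <- bezier_polyline(p0, ctrl, p1)
      poly[, 1] <- pmin(pmax(poly[, 1], 0.5), H + 0.5)
      poly[, 2] <- pmin(pmax(poly[, 2], 0.5), W + 0.5)
      poly
    } else {
      rbind(p0, p1)
    }
  } else {
    len_px <- runif(1, spec$fiber_length_um[1], spec$fiber_length_um[2]) /
      spec$um_per_px
    theta <- runif(1, 0, pi)
    u <- c(sin(theta), cos(theta))
    ctr <- c(runif(1, 1, H), runif(1, 1, W))
    rbind(ctr - u * len_px / 2, ctr + u * len_px / 2)
  }
}

segment_fits <- function(poly, margin, row_max, W) {
  all(poly[, 1] >= 1 + margin) && all(poly[, 1] <= row_max - margin) &&
    all(poly[, 2] >= 1 + margin) && all(poly[, 2] <= W - margin)
}

#' Generate a synthetic fiber-mesh micrograph with exact ground truth
#'
#' Draws fibers as constant-width strokes along straight (or gently bowed)
#' centerlines, records the exact per-fiber centerlines, diameters and an
#' analytic total lateral surface area `sum(pi * d_f * L_f)` under the
#' cylindrical-fiber model, freezes the binary ground-truth masks, and only
#' then applies intensity noise. Identical `spec` (including its seed)
#' reproduces the image and truth bit-for-bit.
#'
#' Overlap convention: when fibers may overlap, the fiber mask is the union
#' of strokes while the ground-truth totals count every fiber in full
#' (projection convention), so mask-based estimators are biased low on
#' dense meshes; use `allow_overlap = FALSE` for unbiased validation.
#'
#' @param spec A [mesh_spec()].
#' @param max_tries Placement attempts per fiber before giving up when
#'   `allow_overlap = FALSE`.
#' @return A list with class `mesh_sim`:
#'   \describe{
#'     \item{image}{numeric matrix in `[0, 1]`, `image_height_px` rows.}
#'     \item{truth}{`mesh_truth` object: `fibers` (list of
#'       `polyline_px`, `diameter_um`, `length_um`), `fiber_mask`,
#'       `void_mask`, `label` (integer matrix of fiber ids, later fibers on
#'       top), `total_centerline_length_um`, `analytic_surface_area_um2`,
#'       `fiber_area_fraction`, `seed`.}
#'   }
#' @examples
#' sim <- generate_mesh(mesh_spec(256, 256, n_fibers = 5, seed = 3))
#' sim$truth$fiber_area_fraction
#' @export
generate_mesh <- function(spec, max_tries = 500) {
  spec <- validate_mesh_spec(spec)
  H <- spec$image_height_px; W <- spec$image_width_px
  bar_margin <- if (!is.null(spec$scale_bar))
    as.integer(spec$scale_bar$thickness_px + 16L) else 0L
  row_max <- H - bar_margin
  if (row_max < 8L) fm_stop_validation("scale-bar margin leaves no room for fibers")

  with_seed(spec$seed, {
    d_um <- draw_diameters(spec$law, spec$n_fibers)
    union <- matrix(FALSE, H, W)
    label <- matrix(0L, H, W)
    fibers <- vector("list", spec$n_fibers)
    for (k in seq_len(spec$n_fibers)) {
      r_px <- (d_um[k] / spec$um_per_px) / 2
      placed <- FALSE
      for (i in seq_len(max_tries)) {
        poly <- propose_polyline(spec, row_max, W)
        if (spec$placement == "segment" &&
            !segment_fits(poly, r_px + spec$overlap_margin_px + 1, row_max, W))
          next
        if (!spec$allow_overlap) {
          guard <- rasterize_polyline(poly, r_px + spec$overlap_margin_px,
                                      H, W, row_max)
          if (any(union[guard])) next
        }
        pix <- rasterize_polyline(poly, r_px, H, W, row_max)
        union[pix] <- TRUE
        label[pix] <- k
        fibers[[k]] <- list(
          polyline_px = unname(poly), diameter_um = d_um[k],
          length_um = polyline_length_px(poly) * spec$um_per_px)
        placed <- TRUE
        break
      }
      if (!placed)
        fm_stop_computation(sprintf(
          "could not place fiber %d without overlap after %d tries; lower n_fibers or fiber_length_um",
          k, max_tries))
    }

    lengths_um <- vapply(fibers, function(f) f$length_um, 0)
    img <- matrix(spec$bg_intensity, H, W)
    img[union] <- spec$fg_intensity
    if (!is.null(spec$scale_bar)) {
      bar_px <- round(spec$scale_bar$length_um / spec$um_per_px)
      th <- spec$scale_bar$thickness_px
      r0 <- H - 8L - th + 1L
      c0 <- max(1L, (W - bar_px) %/% 2L)
      img[r0:(r0 + th - 1L), c0:min(W, c0 + bar_px - 1L)] <- 1
    }
    if (spec$noise_sd > 0) {
      img <- img + rnorm(length(img), sd = spec$noise_sd)
      img <- matrix(pmin(pmax(img, 0), 1), H, W)
    }

    truth <- structure(list(
      fibers = fibers,
      fiber_mask = union,
      void_mask = !union,
      label = label,
      total_centerline_length_um = sum(lengths_um),
      analytic_surface_area_um2 = sum(pi * d_um * lengths_um),
      fiber_area_fraction = sum(union) / (H * W),
      um_per_px = spec$um_per_px,
      seed = spec$seed
    ), class = "mesh_truth")
    structure(list(image = img, truth = truth, spec = spec),
              class = "mesh_sim")
  })
}

#' Render fibers with explicit centerlines
#'
#' Lower-level companion to [generate_mesh()] for deterministic geometries
#' (e.g. a single horizontal fiber with known analytic coverage). Takes
#' centerline polylines in pixel coordinates and diameters in micrometers
#' and produces the same image/truth structure, with no randomness except
#' the optional noise.
#'
#' @param polylines List of 2-column matrices `(row, col)` in pixel
#'   coordinates.
#' @param diameters_um Numeric vector, one diameter per polyline.
#' @param spec A [mesh_spec()] supplying image size, scale and intensities;
#'   its `n_fibers`, law and placement fields are ignored.
#' @return A `mesh_sim` list as in [generate_mesh()].
#' @export
render_mesh <- function(polylines, diameters_um, spec) {
  if (length(polylines) != length(diameters_um))
    fm_stop_validation("'polylines' and 'diameters_um' must have equal length")
  H <- spec$image_height_px; W <- spec$image_width_px
  union <- matrix(FALSE, H, W)
  label <- matrix(0L, H, W)
  fibers <- vector("list", length(polylines))
  for (k in seq_along(polylines)) {
    poly <- polylines[[k]]
    r_px <- (diameters_um[k] / spec$um_per_px) / 2
    pix <- rasterize_polyline(poly, r_px, H, W)
    union[pix] <- TRUE
    label[pix] <- k
    fibers[[k]] <- list(polyline_px = unname(poly),
                        diameter_um = diameters_um[k],
                        length_um = polyline_length_px(poly) * spec$um_per_px)
  }
  lengths_um <- vapply(fibers, function(f) f$length_um, 0)
  img <- matrix(spec$bg_intensity, H, W)
  img[union] <- spec$fg_intensity
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed, img + rnorm(length(img), sd = spec$noise_sd))
    img <- matrix(pmin(pmax(img, 0), 1), H, W)
  }
  truth <- structure(list(
    fibers = fibers, fiber_mask = union, void_mask = !union, label = label,
    total_centerline_length_um = sum(lengths_um),
    analytic_surface_area_um2 = sum(pi * diameters_um * lengths_um),
    fiber_area_fraction = sum(union) / (H * W),
    um_per_px = spec$um_per_px, seed = spec$seed
  ), class = "mesh_truth")
  structure(list(image = img, truth = truth, spec = spec), class = "mesh_sim")
}

#' Write / read mesh ground truth
#'
#' Ground truth is persisted as JSON (per-fiber polylines, diameters and
#' totals) plus an optional 16-bit label TIFF of fiber ids (0 =
#' background; ids recovered as `round(value * 65535)`).
#'
#' @param truth A `mesh_truth` object.
#' @param json_path Output JSON path.
#' @param label_tiff_path Optional output path for the label image.
#' @return `json_path`, invisibly.
#' @export
write_mesh_truth <- function(truth, json_path, label_tiff_path = NULL) {
  payload <- list(
    um_per_px = truth$um_per_px,
    seed = truth$seed,
    total_centerline_length_um = truth$total_centerline_length_um,
    analytic_surface_area_um2 = truth$analytic_surface_area_um2,
    fiber_area_fraction = truth$fiber_area_fraction,
    fibers = lapply(truth$fibers, function(f) list(
      diameter_um = f$diameter_um, length_um = f$length_um,
      polyline_px = f$polyline_px))
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(label_tiff_path)) {
    if (max(truth$label) > 65535L)
      fm_stop_io("more than 65535 fibers cannot be stored in a 16-bit label image")
    tiff::writeTIFF(truth$label / 65535, label_tiff_path,
                    bits.per.sample = 16L)
  }
  invisible(json_path)
}

#' @rdname write_mesh_truth
#' @export
read_mesh_truth <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  x$fibers <- lapply(seq_len(nrow_safe(x$fibers)), function(i) list(
    diameter_um = x$fibers$diameter_um[i],
    length_um = x$fibers$length_um[i],
    polyline_px = matrix(unlist(x$fibers$polyline_px[i]), ncol = 2)))
  x
}

nrow_safe <- function(x) if (is.null(x) || is.null(nrow(x))) 0L else nrow(x)

#' @export
print.mesh_truth <- function(x, ...) {
  cat(sprintf("<mesh_truth> %d fibers, total length %.1f um, area fraction %.3f\n",
              length(x$fibers), x$total_centerline_length_um,
              x$fiber_area_fraction))
  cat(sprintf("  analytic surface area %.1f um^2 (cylindrical model)\n",
              x$analytic_surface_area_um2))
  invisible(x)
}
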