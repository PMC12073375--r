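#' Binarize a calibrated micrograph
#'
#' Thresholds a `[0, 1]` grayscale image into a fiber mask, fibers assumed
#' bright on a dark background (pixels with intensity >= threshold are
#' foreground). The default threshold is Otsu's method; a fixed threshold
#' is available for strict reproducibility across reanalyses.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold in `[0, 1]` when `method = "fixed"`.
#' @return A `fiber_mask` object: logical matrix `mask` plus threshold
#'   provenance.
#' @export
binarize <- function(image, method = c("otsu", "fixed"),
                     fixed_threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image))
    fm_stop_validation("'image' must be a numeric matrix")
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    fm_stop_validation("'image' intensities must lie in [0, 1]")
  thr <- if (method == "otsu") {
    if (diff(range(image)) < 1e-6)
      fm_stop_computation("no foreground/background separation: image is constant")
    EBImage::otsu(EBImage::Image(image), range = c(0, 1), levels = 256L)
  } else {
    check_scalar(fixed_threshold, "fixed_threshold", nonneg = TRUE)
    fixed_threshold
  }
  structure(list(mask = image >= thr, method = method, threshold = thr,
                 cleanup = NULL),
            class = "fiber_mask")
}

as_mask_matrix <- function(x) {
  if (inherits(x, "fiber_mask")) return(x$mask)
  if (is.matrix(x) && is.logical(x)) return(x)
  if (is.matrix(x) && is.numeric(x)) return(x > 0.5)
  fm_stop_validation("expected a fiber_mask object or a logical matrix")
}

#' @export
print.fiber_mask <- function(x, ...) {
  cat(sprintf("<fiber_mask> %d x %d px, coverage %.3f (%s threshold %.4g)\n",
              nrow(x$mask), ncol(x$mask), mean(x$mask), x$method, x$threshold))
  invisible(x)
}

#' Remove speckle and close small gaps in a fiber mask
#'
#' Applies morphological closing (disc brush of the given radius), then
#' removes 8-connected foreground components smaller than `min_object_px`.
#' Degenerate parameters (0) are no-ops and re-application with the same
#' parameters leaves the mask unchanged.
#'
#' @param mask A `fiber_mask` or logical matrix.
#' @param min_object_px Minimum component size kept, in pixels (>= 0).
#' @param closing_radius_px Closing brush radius in pixels (>= 0).
#' @return A `fiber_mask`.
#' @export
clean_mask <- function(mask, min_object_px = 0L, closing_radius_px = 0L) {
  check_scalar(min_object_px, "min_object_px", nonneg = TRUE, integerish = TRUE)
  check_scalar(closing_radius_px, "closing_radius_px", nonneg = TRUE,
               integerish = TRUE)
  fm <- if (inherits(mask, "fiber_mask")) mask else
    structure(list(mask = as_mask_matrix(mask), method = "external",
                   threshold = NA_real_, cleanup = NULL),
              class = "fiber_mask")
  m <- fm$mask
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * closing_radius_px + 1L, shape = "disc")
    m <- EBImage::closing(m * 1, brush) > 0.5
  }
  if (min_object_px > 0 && any(m)) {
    lab <- EBImage::bwlabel(m * 1)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_object_px)
    if (length(drop)) m[lab %in% drop] <- FALSE
  }
  fm$mask <- matrix(as.logical(m), nrow(fm$mask), ncol(fm$mask))
  fm$cleanup <- list(min_object_px = min_object_px,
                     closing_radius_px = closing_radius_px)
  fm
}

# --- skeleton internals ----------------------------------------------------

# Undirected 8-neighbour step list over a skeleton matrix, each pair once.
# Diagonal steps sharing an axial pixel with both endpoints are suppressed
# (the chain already passes through that pixel), so an L-shaped path of
# 2n axial steps has length exactly 2n.
skeleton_edges <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- list()
  add <- function(dr, dc, w) {
    rA <- seq_len(H - dr)
    cA <- if (dc >= 0) seq_len(W - dc) else seq.int(1 - dc, W)
    A <- m[rA, cA, drop = FALSE]
    B <- m[rA + dr, cA + dc, drop = FALSE]
    keep <- A & B
    if (w > 1) {
      C <- m[rA, cA + dc, drop = FALSE]
      D <- m[rA + dr, cA, drop = FALSE]
      keep <- keep & !(C | D)
    }
    ij <- which(keep, arr.ind = TRUE)
    if (nrow(ij) == 0L) return(NULL)
    r1 <- ij[, 1]; c1 <- cA[ij[, 2]]
    cbind(r1 = r1, c1 = c1, r2 = r1 + dr, c2 = c1 + dc, w = w)
  }
  out <- list(add(0L, 1L, 1), add(1L, 0L, 1),
              add(1L, 1L, sqrt(2)), add(1L, -1L, sqrt(2)))
  out <- do.call(rbind, out)
  if (is.null(out)) out <- matrix(numeric(0), 0, 5,
                                  dimnames = list(NULL,
                                    c("r1", "c1", "r2", "c2", "w")))
  out
}

build_skeleton <- function(m, um_per_px = NA_real_, prune_px = 0L) {
  H <- nrow(m); W <- ncol(m)
  edges <- skeleton_edges(m)
  coords <- which(m, arr.ind = TRUE)
  ids <- coords[, 1] + (coords[, 2] - 1L) * H
  deg <- integer(length(ids))
  if (nrow(edges)) {
    e1 <- edges[, "r1"] + (edges[, "c1"] - 1) * H
    e2 <- edges[, "r2"] + (edges[, "c2"] - 1) * H
    tab <- table(factor(c(e1, e2), levels = ids))
    deg <- as.integer(tab)
  }
  structure(list(
    mask = m, dim = c(H, W),
    coords = unname(coords), pixel_ids = as.numeric(ids),
    degree = deg,
    endpoint = deg == 1L, junction = deg >= 3L,
    border = coords[, 1] <= 1L | coords[, 1] >= H |
             coords[, 2] <= 1L | coords[, 2] >= W,
    edges = edges,
    n_axial_steps = sum(edges[, "w"] == 1),
    n_diag_steps = sum(edges[, "w"] > 1),
    total_length_px = sum(edges[, "w"]),
    um_per_px = um_per_px,
    prune_px = prune_px
  ), class = "fiber_skeleton")
}

# Chain-adjacent neighbours of a skeleton pixel: axial neighbours always,
# diagonal neighbours only when no shared axial skeleton pixel shortcuts
# them (same suppression rule as skeleton_edges).
chain_neighbours <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, 0, 2)
  at <- function(rr, cc) rr >= 1L && rr <= H && cc >= 1L && cc <= W && m[rr, cc]
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rr <- r + dr; cc <- c + dc
    if (!at(rr, cc)) next
    if (dr != 0L && dc != 0L && (at(r, cc) || at(rr, c))) next
    out <- rbind(out, c(rr, cc))
  }
  out
}

# Remove spur branches: endpoint-to-junction paths of at most prune_px
# pixels. Free paths (endpoint to endpoint) are real fibers and are kept.
prune_spurs <- function(m, prune_px) {
  if (prune_px <= 0) return(m)
  H <- nrow(m)
  for (pass in 1:4) {
    sk <- build_skeleton(m)
    if (!any(sk$endpoint) || !any(sk$junction)) return(m)
    deg <- matrix(0L, H, ncol(m))
    deg[sk$pixel_ids] <- sk$degree
    to_drop <- numeric(0)
    eps <- sk$coords[sk$endpoint, , drop = FALSE]
    for (i in seq_len(nrow(eps))) {
      cur <- eps[i, ]
      prev <- c(NA_integer_, NA_integer_)
      path <- cur[1] + (cur[2] - 1) * H
      repeat {
        nb <- chain_neighbours(m, cur[1], cur[2])
        if (!is.na(prev[1]))
          nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nb) != 1L) break  # isolated pixel or immediate junction
        nxt <- nb[1, ]
        dn <- deg[nxt[1], nxt[2]]
        if (dn >= 3L) {  # reached a junction: this was a spur
          if (length(path) <= prune_px) to_drop <- c(to_drop, path)
          break
        }
        if (dn == 1L) break  # free endpoint-to-endpoint path, keep
        path <- c(path, nxt[1] + (nxt[2] - 1) * H)
        if (length(path) > prune_px) break
        prev <- cur
        cur <- nxt
      }
    }
    if (!length(to_drop)) return(m)
    m[to_drop] <- FALSE
  }
  m
}

#' Skeletonize a fiber mask
#'
#' Topology-preserving thinning (Zhang-Suen, with a staircase cleanup that
#' guarantees no fully-set 2x2 block survives) reduces fibers to
#' 1-pixel-wide centerlines; spur branches shorter than `prune_px` pixels
#' (thinning artifacts at fiber edges) are then removed. An empty mask
#' yields an empty skeleton, not an error.
#'
#' @param mask A `fiber_mask` or logical matrix.
#' @param prune_px Maximum spur length removed, in pixels.
#' @param calibration Optional [calibration()] (or um/px value) recorded in
#'   the skeleton for later length conversion.
#' @return A `fiber_skeleton`: pixel coordinates, 8-neighbour step list
#'   with weights (1 axial, sqrt(2) diagonal), per-pixel degree with
#'   endpoint/junction/border flags, and total length in pixel units.
#' @export
skeletonize_mask <- function(mask, prune_px = 5L, calibration = NULL) {
  check_scalar(prune_px, "prune_px", nonneg = TRUE, integerish = TRUE)
  m <- as_mask_matrix(mask)
  upp <- if (is.null(calibration)) NA_real_ else as_calibration(calibration)$um_per_px
  if (!any(m)) return(build_skeleton(m, upp, prune_px))
  sk <- .thin_zhang_suen(m)
  sk <- prune_spurs(sk, prune_px)
  build_skeleton(sk, upp, prune_px)
}

#' Treat an already-thin centerline mask as a skeleton
#'
#' Builds the skeleton graph (steps, degrees, endpoint/junction flags)
#' directly from a mask that is already one pixel wide, e.g. a centerline
#' exported by another tool, without thinning or pruning it.
#'
#' @param mask Logical matrix of centerline pixels.
#' @param calibration Optional [calibration()] or um/px value.
#' @return A `fiber_skeleton`.
#' @export
as_skeleton <- function(mask, calibration = NULL) {
  m <- as_mask_matrix(mask)
  upp <- if (is.null(calibration)) NA_real_ else as_calibration(calibration)$um_per_px
  build_skeleton(m, upp, 0L)
}

#' @export
print.fiber_skeleton <- function(x, ...) {
  cat(sprintf("<fiber_skeleton> %d px, %d endpoints, %d junctions, length %.1f px",
              nrow(x$coords), sum(x$endpoint), sum(x$junction),
              x$total_length_px))
  if (!is.na(x$um_per_px))
    cat(sprintf(" = %.2f um", x$total_length_px * x$um_per_px))
  cat("\n")
  invisible(x)
}

#' Total centerline length in micrometers
#'
#' Sums the skeleton's 8-connected steps, each undirected step counted
#' once with weight 1 (axial) or sqrt(2) (diagonal), and converts to
#' micrometers. `length_mode = "pixel_count"` instead counts skeleton
#' pixels (weight 1 each), a compatibility option matching plain
#' pixel-counting measurements.
#'
#' @param skeleton A `fiber_skeleton`.
#' @param calibration A [calibration()] or um/px value; defaults to the
#'   calibration stored in the skeleton.
#' @param length_mode `"weighted"` (default) or `"pixel_count"`.
#' @return Length in micrometers (>= 0).
#' @export
total_length <- function(skeleton, calibration = NULL,
                         length_mode = c("weighted", "pixel_count")) {
  length_mode <- match.arg(length_mode)
  if (!inherits(skeleton, "fiber_skeleton"))
    fm_stop_validation("'skeleton' must be a fiber_skeleton")
  upp <- if (is.null(calibration)) skeleton$um_per_px
         else as_calibration(calibration)$um_per_px
  if (is.na(upp))
    fm_stop_validation("no calibration available for length conversion")
  px <- if (length_mode == "weighted") skeleton$total_length_px
        else nrow(skeleton$coords)
  px * upp
}

#' Export a skeleton as a JSON graph
#'
#' Nodes are skeleton pixels typed as `end`, `junction` or `regular`;
#' edges carry their step weight in pixels.
#'
#' @param skeleton A `fiber_skeleton`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_skeleton_graph <- function(skeleton, path) {
  type <- ifelse(skeleton$endpoint, "end",
                 ifelse(skeleton$junction, "junction", "regular"))
  payload <- list(
    dim = skeleton$dim,
    um_per_px = skeleton$um_per_px,
    nodes = data.frame(row = skeleton$coords[, 1],
                       col = skeleton$coords[, 2], type = type),
    edges = as.data.frame(skeleton$edges)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
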