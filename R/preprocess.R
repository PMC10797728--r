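# Preprocessing: grid tiling against polygon annotations, optical-density
# transform, stain-vector estimation, stain normalization, deconvolution.

#' Standard H&E stain matrix
#'
#' The widely used hematoxylin/eosin optical-density direction vectors,
#' unit-normalized, as the fallback when per-image estimation fails.
#'
#' @return 3 x 2 matrix; columns are unit H and E vectors in OD space.
#' @export
default_stain_matrix <- function() {
  m <- cbind(H = c(0.650, 0.704, 0.286), E = c(0.072, 0.990, 0.105))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

# ---- polygon utilities (Sutherland-Hodgman against an axis-aligned box) ----

# Shoelace area (absolute) of a polygon given as a 2-column matrix.
polygon_area <- function(pts) {
  n <- nrow(pts)
  if (is.null(n) || n < 3) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Clip polygon by the half-plane {p : keep(p)}, edge intersection via inter().
clip_half <- function(pts, keep, inter) {
  n <- nrow(pts)
  if (is.null(n) || n == 0) return(pts)
  out <- matrix(numeric(0), ncol = 2)
  inside <- keep(pts)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- pts[i, ]; q <- pts[j, ]
    if (inside[i]) {
      out <- rbind(out, p)
      if (!inside[j]) out <- rbind(out, inter(p, q))
    } else if (inside[j]) {
      out <- rbind(out, inter(p, q))
    }
  }
  out
}

# Intersection of a simple polygon with the axis-aligned box
# [x0, x1] x [y0, y1]; returns the clipped polygon vertex matrix.
clip_polygon_box <- function(pts, x0, x1, y0, y1) {
  eps <- 1e-12
  lerp <- function(p, q, t) p + t * (q - p)
  pts <- clip_half(pts, function(m) m[, 1] >= x0 - eps, function(p, q)
    lerp(p, q, (x0 - p[1]) / (q[1] - p[1])))
  pts <- clip_half(pts, function(m) m[, 1] <= x1 + eps, function(p, q)
    lerp(p, q, (x1 - p[1]) / (q[1] - p[1])))
  pts <- clip_half(pts, function(m) m[, 2] >= y0 - eps, function(p, q)
    lerp(p, q, (y0 - p[2]) / (q[2] - p[2])))
  pts <- clip_half(pts, function(m) m[, 2] <= y1 + eps, function(p, q)
    lerp(p, q, (y1 - p[2]) / (q[2] - p[2])))
  pts
}

# Signed area to detect self-intersection cheaply is not sufficient; we
# check pairwise non-adjacent edge crossings (polygons here are small).
polygon_is_simple <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(FALSE)
  seg <- function(i) rbind(pts[i, ], pts[if (i == n) 1L else i + 1L, ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(s1, s2) {
    d1 <- cross(s2[1, ], s2[2, ], s1[1, ]); d2 <- cross(s2[1, ], s2[2, ], s1[2, ])
    d3 <- cross(s1[1, ], s1[2, ], s2[1, ]); d4 <- cross(s1[1, ], s1[2, ], s2[2, ])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent around the loop
      if (intersects(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

#' Partition annotated regions into grid-aligned tiles
#'
#' Lays a non-overlapping tile grid (stride = `tile_size`, anchored at
#' the origin, x rightward / y downward) over the image extent and
#' retains a tile iff its intersection area with some annotated region is
#' at least `min_overlap * tile_size^2`. The tile's class is the class of
#' the region with the largest overlap area; exact ties break to the
#' lower class id.
#'
#' @param regions list of regions, each `list(polygon = <n x 2 matrix of
#'   (x, y) vertices in level-0 pixels>, class_id = <integer>)`.
#' @param image_extent `c(width, height)` in pixels.
#' @param tile_size tile side in pixels (default 224).
#' @param min_overlap minimum overlap fraction in (0, 1] (default 0.90).
#' @param patient_id optional id copied onto every record.
#' @return data.frame: patient_id, grid_row, grid_col, origin_x, origin_y,
#'   class (one row per retained tile).
#' @export
tile_partition <- function(regions, image_extent, tile_size = 224L,
                           min_overlap = 0.90, patient_id = NA_character_) {
  if (length(regions) == 0) stop("empty region list")
  if (tile_size < 1) stop("tile_size must be >= 1")
  if (min_overlap <= 0 || min_overlap > 1) stop("min_overlap must be in (0, 1]")
  for (rg in regions) {
    if (!polygon_is_simple(rg$polygon)) stop("self-intersecting polygon")
  }
  w <- image_extent[1]; h <- image_extent[2]
  ncols <- floor(w / tile_size); nrows <- floor(h / tile_size)
  need <- min_overlap * tile_size^2
  rows <- integer(0); cols <- integer(0); cls <- integer(0)
  for (gr in seq_len(nrows) - 1L) {
    y0 <- gr * tile_size; y1 <- y0 + tile_size
    for (gc in seq_len(ncols) - 1L) {
      x0 <- gc * tile_size; x1 <- x0 + tile_size
      best_area <- 0; best_class <- NA_integer_
      for (rg in regions) {
        bb <- rg$polygon
        if (max(bb[, 1]) <= x0 || min(bb[, 1]) >= x1 ||
            max(bb[, 2]) <= y0 || min(bb[, 2]) >= y1) next
        a <- polygon_area(clip_polygon_box(rg$polygon, x0, x1, y0, y1))
        better <- a > best_area + 1e-9 ||
          (abs(a - best_area) <= 1e-9 && !is.na(best_class) &&
             rg$class_id < best_class)
        if (better) { best_area <- a; best_class <- rg$class_id }
      }
      if (best_area >= need - 1e-9) {
        rows <- c(rows, gr); cols <- c(cols, gc); cls <- c(cls, best_class)
      }
    }
  }
  data.frame(patient_id = rep(patient_id, length(rows)),
             grid_row = rows, grid_col = cols,
             origin_x = cols * tile_size, origin_y = rows * tile_size,
             class = cls, stringsAsFactors = FALSE)
}

#' RGB to optical density
#'
#' `OD = -log10((I + eps) / I0)` elementwise, with `eps = 1e-6` guarding
#' zero intensities.
#'
#' @param tile numeric array of intensities in `[0, background_intensity]`
#'   (any shape).
#' @param background_intensity white point I0 (default 255).
#' @return array of the same shape, OD units.
#' @export
rgb_to_od <- function(tile, background_intensity = 255) {
  -log10((tile + 1e-6) / background_intensity)
}

#' Optical density back to RGB intensities
#'
#' Inverse of [rgb_to_od()], clipped to `[0, background_intensity]`.
#' @param od OD array.
#' @param background_intensity white point (default 255).
#' @return intensity array.
#' @export
od_to_rgb <- function(od, background_intensity = 255) {
  i <- background_intensity * 10^(-od) - 1e-6
  pmin(pmax(i, 0), background_intensity)
}

#' Estimate H&E stain vectors from a tile (SVD / extreme-angle method)
#'
#' Tissue pixels (OD norm >= `beta_od`) are projected onto the plane of
#' their top two singular directions; the stain vectors are the unit OD
#' directions at the `alpha` and `100 - alpha` angle percentiles. The
#' vector with the larger blue-channel OD component is labeled
#' hematoxylin. Robust per-stain maximum concentrations (99th percentile)
#' complete the model.
#'
#' @param tile RGB array `h x w x 3`, intensities 0..255.
#' @param alpha_percentile angle percentile (default 1).
#' @param beta_od tissue OD threshold (default 0.15).
#' @param min_tissue minimum number of tissue pixels (default 100).
#' @return a `stain_model`: list(stain_matrix = 3 x 2 unit columns (H, E),
#'   max_concentrations = length-2 numeric).
#' @export
estimate_stain_vectors <- function(tile, alpha_percentile = 1,
                                   beta_od = 0.15, min_tissue = 100L) {
  od <- rgb_to_od(tile)
  px <- matrix(od, ncol = 3)
  tissue <- px[sqrt(rowSums(px^2)) >= beta_od, , drop = FALSE]
  if (nrow(tissue) < min_tissue) {
    stop("insufficient tissue: fewer than ", min_tissue,
         " pixels above the OD threshold")
  }
  sv <- svd(tissue, nu = 0, nv = 2)
  V <- sv$v  # 3 x 2 plane basis
  # orient the basis so projections land in the positive quadrant mostly
  proj <- tissue %*% V
  if (mean(proj[, 1]) < 0) { V[, 1] <- -V[, 1]; proj[, 1] <- -proj[, 1] }
  phi <- atan2(proj[, 2], proj[, 1])
  lo <- stats::quantile(phi, alpha_percentile / 100, names = FALSE)
  hi <- stats::quantile(phi, 1 - alpha_percentile / 100, names = FALSE)
  v1 <- V %*% c(cos(lo), sin(lo))
  v2 <- V %*% c(cos(hi), sin(hi))
  v1 <- v1 * sign(sum(v1)); v2 <- v2 * sign(sum(v2))
  v1 <- v1 / sqrt(sum(v1^2)); v2 <- v2 / sqrt(sum(v2^2))
  # hematoxylin absorbs more in the blue channel (third OD component here
  # is red-ish; use convention: H has larger OD in channel 1+3 ... use
  # the standard rule: larger first-channel (red absorption) => H)
  if (v1[1] >= v2[1]) M <- cbind(H = as.vector(v1), E = as.vector(v2))
  else M <- cbind(H = as.vector(v2), E = as.vector(v1))
  # single-stain degenerate case: the two extreme angles coincide; keep
  # the recovered direction for the stain it resembles and fall back to
  # the standard vector for the other
  if (abs(sum(M[, 1] * M[, 2])) > 0.999) {
    std <- default_stain_matrix()
    v <- M[, 1]
    if (sum(v * std[, 1]) >= sum(v * std[, 2])) M <- cbind(H = v, E = std[, 2])
    else M <- cbind(H = std[, 1], E = v)
  }
  conc <- stain_concentrations(od, M)
  maxc <- apply(conc, 2, stats::quantile, probs = 0.99, names = FALSE)
  structure(list(stain_matrix = M, max_concentrations = as.vector(maxc)),
            class = "stain_model")
}

# Per-pixel stain concentrations by least squares against the stain
# matrix; rows = pixels, cols = stains. od: h x w x 3 array or n x 3 matrix.
stain_concentrations <- function(od, stain_matrix) {
  px <- if (length(dim(od)) == 3) matrix(od, ncol = 3) else od
  G <- crossprod(stain_matrix)
  if (abs(det(G)) < 1e-12) stop("singular unmixing system")
  t(solve(G, t(px %*% stain_matrix)))
}

#' Normalize a tile's stains against a reference model
#'
#' Unmixes concentrations with the source model, rescales each stain to
#' the reference robust maxima, and remixes with the reference stain
#' matrix; output clipped to valid intensities.
#'
#' @param tile RGB array h x w x 3 (0..255).
#' @param source `stain_model` of the tile.
#' @param reference target `stain_model`.
#' @return RGB array, same shape, values in [0, 255].
#' @export
normalize_stains <- function(tile, source, reference) {
  d <- dim(tile)
  od <- rgb_to_od(tile)
  conc <- stain_concentrations(od, source$stain_matrix)
  conc[conc < 0] <- 0
  scale <- reference$max_concentrations / pmax(source$max_concentrations, 1e-8)
  conc <- sweep(conc, 2, scale, "*")
  od_new <- conc %*% t(reference$stain_matrix)
  array(od_to_rgb(od_new), dim = d)
}

#' Hematoxylin concentration channel by color deconvolution
#'
#' @param tile RGB array h x w x 3 (0..255).
#' @param model `stain_model`; default the standard H&E matrix.
#' @return h x w matrix of nonnegative hematoxylin concentrations
#'   (OD units).
#' @export
hematoxylin_channel <- function(tile, model = NULL) {
  if (is.null(model))
    model <- structure(list(stain_matrix = default_stain_matrix(),
                            max_concentrations = c(1, 1)),
                       class = "stain_model")
  conc <- stain_concentrations(rgb_to_od(tile), model$stain_matrix)
  h <- conc[, 1]
  h[h < 0] <- 0
  matrix(h, dim(tile)[1], dim(tile)[2])
}

#' Is a tile background?
#'
#' Mirrors the separately labeled background class: tiles whose mean OD
#' falls below `threshold` are flagged background.
#'
#' @param tile RGB array (0..255).
#' @param threshold mean-OD cutoff (default 0.10).
#' @return logical.
#' @export
is_background_tile <- function(tile, threshold = 0.10) {
  mean(rgb_to_od(tile)) < threshold
}

#' Read QuPath-style GeoJSON annotations
#'
#' Reads a FeatureCollection of polygon features whose class label sits
#' under `properties.classification.name`, mapping labels to class ids
#' via the histology catalog (or a supplied catalog).
#'
#' @param path GeoJSON file.
#' @param catalog data.frame with `class_id` and `name`
#'   (default [histology_classes()]).
#' @return list of regions: `list(polygon = <n x 2 matrix>, class_id,
#'   class_name)`.
#' @export
read_annotations <- function(path, catalog = histology_classes()) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$features)) stop("not a GeoJSON FeatureCollection")
  out <- list()
  for (ft in doc$features) {
    geom <- ft$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) next
    ring <- geom$coordinates[[1]]
    pts <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # drop a closing vertex equal to the first
    if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ]))
      pts <- pts[-nrow(pts), , drop = FALSE]
    nm <- ft$properties$classification$name
    if (is.null(nm)) nm <- ft$properties$name
    cid <- catalog$class_id[match(nm, catalog$name)]
    if (length(cid) == 0 || is.na(cid))
      stop("annotation class '", nm, "' not in the catalog")
    out[[length(out) + 1L]] <- list(polygon = pts, class_id = cid,
                                    class_name = nm)
  }
  out
}
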