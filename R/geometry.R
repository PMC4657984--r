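# Planar polygon utilities for crown geometry.
#
# Polygons are numeric n x 2 matrices (columns x, y, map units in meters),
# open rings: the first vertex is NOT repeated at the end. Orientation is
# free on input; functions normalise to counter-clockwise where it matters.

#' Polygon area (shoelace formula)
#'
#' @param poly Numeric n x 2 matrix of vertices (open ring).
#' @return Area in squared map units (always >= 0).
#' @export
poly_area <- function(poly) {
  poly <- check_poly(poly)
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' Polygon perimeter
#' @inheritParams poly_area
#' @return Perimeter in map units.
#' @export
poly_perimeter <- function(poly) {
  poly <- check_poly(poly)
  d <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]) - poly
  sum(sqrt(rowSums(d^2)))
}

check_poly <- function(poly) {
  if (is.data.frame(poly)) poly <- as.matrix(poly)
  if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3 ||
      !is.numeric(poly) || anyNA(poly)) {
    stop("polygon must be a numeric matrix with >= 3 rows and 2 columns (x, y)",
         call. = FALSE)
  }
  # drop a duplicated closing vertex if the ring was supplied closed
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3) {
    stop("polygon degenerates to fewer than 3 distinct vertices", call. = FALSE)
  }
  unname(poly)
}

# signed area: > 0 for counter-clockwise rings
poly_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

poly_ccw <- function(poly) {
  if (poly_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Test whether a polygon is convex
#' @inheritParams poly_area
#' @return Logical scalar. Collinear consecutive edges are allowed.
#' @export
poly_is_convex <- function(poly) {
  poly <- check_poly(poly)
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  c_ <- poly[c(3:n, 1, 2), , drop = FALSE]
  cr <- (b[, 1] - a[, 1]) * (c_[, 2] - b[, 2]) -
        (b[, 2] - a[, 2]) * (c_[, 1] - b[, 1])
  cr <- cr[abs(cr) > 1e-12]
  length(cr) == 0 || all(cr > 0) || all(cr < 0)
}

# Simple-polygon validity: >= 3 distinct vertices, positive area, and no two
# non-adjacent edges intersecting (O(n^2), crowns have few vertices).
poly_is_valid <- function(poly) {
  poly <- tryCatch(check_poly(poly), error = function(e) NULL)
  if (is.null(poly)) return(FALSE)
  if (poly_area(poly) <= 0) return(FALSE)
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next  # adjacent edges share a vertex
      if (segments_intersect(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(a, b, c) {
    o(a, b, c) == 0 &&
      min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  on_seg(p1, p2, q1) || on_seg(p1, p2, q2) || on_seg(q1, q2, p1) || on_seg(q1, q2, p2)
}

#' Vectorised even-odd point-in-polygon test
#'
#' @param x,y Numeric vectors of point coordinates.
#' @inheritParams poly_area
#' @return Logical vector; points exactly on the boundary follow the ray
#'   parity and are not guaranteed either way.
#' @export
points_in_polygon <- function(x, y, poly) {
  poly <- check_poly(poly)
  n <- nrow(poly)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Sutherland-Hodgman clip of a polygon against half-plane a*x + b*y <= c.
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  out <- matrix(numeric(0), ncol = 2)
  val <- a * poly[, 1] + b * poly[, 2] - c
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vi <- val[i]; vj <- val[j]
    if (vi <= 1e-12) out <- rbind(out, poly[i, ])
    if ((vi < -1e-12 && vj > 1e-12) || (vi > 1e-12 && vj < -1e-12)) {
      t <- vi / (vi - vj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Narrow a crown polygon by an inward (negative) buffer
#'
#' Shrinks a convex crown delineation inward by `distance` meters, the
#' standard step that strips the mixed-signal crown border before any
#' spectral statistic is computed. Implemented as the intersection of the
#' polygon's edge half-planes offset inward, which is exact for convex
#' polygons (a 2 m square shrunk by 0.5 m is the centred 1 m square).
#'
#' @param poly Convex polygon, numeric n x 2 matrix (meters).
#' @param distance Inward buffer distance in meters, `>= 0` (default 0.5).
#' @return The narrowed polygon, or `NULL` when the buffer swallows the
#'   crown entirely (a valid outcome: the crown is too small and callers
#'   drop it with a warning).
#' @export
narrow_crown <- function(poly, distance = 0.5) {
  poly <- check_poly(poly)
  if (!is.numeric(distance) || length(distance) != 1 || distance < 0) {
    stop("`distance` must be a single non-negative number of meters", call. = FALSE)
  }
  if (distance == 0) return(poly)
  if (!poly_is_convex(poly)) {
    stop("narrow_crown() supports convex crown polygons only; ",
         "re-delineate the crown as a convex outline", call. = FALSE)
  }
  p <- poly_ccw(poly)
  n <- nrow(p)
  out <- p
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- p[j, ] - p[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    nrm <- c(e[2], -e[1]) / len          # outward normal of a CCW ring
    cst <- sum(nrm * p[i, ]) - distance  # edge line pushed inward
    out <- clip_halfplane(out, nrm[1], nrm[2], cst)
    if (nrow(out) < 3) return(NULL)
  }
  if (poly_area(out) < 1e-10) return(NULL)
  unname(out)
}

#' Rasterize a polygon to pixel coordinates by the pixel-center rule
#'
#' Returns the pixels of `layer`'s grid whose center falls inside the
#' polygon. Pixel (0, 0) is the top-left pixel; coordinates are 0-based
#' (row, col). The center of pixel (r, c) sits at map position
#' `(origin_x + (c + 0.5) * gsd, origin_y - (r + 0.5) * gsd)`.
#'
#' @param poly Polygon in the layer's CRS (meters).
#' @param layer A [survey_layer] supplying the grid geometry.
#' @return Integer matrix with columns `row`, `col` (0-based); zero rows
#'   when the polygon misses the raster (reported via a message, not an
#'   error).
#' @export
crown_pixel_mask <- function(poly, layer) {
  poly <- check_poly(poly)
  stopifnot(inherits(layer, "survey_layer"))
  gsd <- layer$gsd
  nr <- dim(layer$bands)[1]; nc <- dim(layer$bands)[2]
  ox <- layer$origin[1]; oy <- layer$origin[2]
  # candidate pixel window from the polygon bounding box
  cmin <- max(0L, floor((min(poly[, 1]) - ox) / gsd - 0.5))
  cmax <- min(nc - 1L, ceiling((max(poly[, 1]) - ox) / gsd - 0.5))
  rmin <- max(0L, floor((oy - max(poly[, 2])) / gsd - 0.5))
  rmax <- min(nr - 1L, ceiling((oy - min(poly[, 2])) / gsd - 0.5))
  if (cmin > cmax || rmin > rmax) {
    message("polygon lies entirely outside the raster; empty mask")
    return(empty_mask())
  }
  cols <- seq.int(cmin, cmax); rows <- seq.int(rmin, rmax)
  grid <- expand.grid(row = rows, col = cols, KEEP.OUT.ATTRS = FALSE)
  cx <- ox + (grid$col + 0.5) * gsd
  cy <- oy - (grid$row + 0.5) * gsd
  keep <- points_in_polygon(cx, cy, poly)
  if (!any(keep)) {
    message("no pixel center falls inside the polygon; empty mask")
    return(empty_mask())
  }
  m <- as.matrix(grid[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

empty_mask <- function() {
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col")))
}

# Random convex crown outline: jittered radial points around a center,
# made convex via the hull so the inward buffer stays exact.
convex_crown_polygon <- function(center, radius, n_vertices = 10, jitter = 0.25) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- radius * (1 + jitter * stats::runif(n_vertices, -1, 1))
  pts <- cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
  hull <- grDevices::chull(pts)
  poly_ccw(pts[hull, , drop = FALSE])
}
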