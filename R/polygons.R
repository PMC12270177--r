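# Polygon primitives for annotation handling.
#
# A polygon is a list with $outer (n x 2 matrix of level-0 pixel coordinates,
# columns x, y) and $holes (list of n x 2 matrices, possibly empty). Rings
# need not be explicitly closed. Rasterization uses the pixel-centre even-odd
# rule: a pixel at (row r, col c) has centre (x = c - 0.5, y = r - 0.5) in
# 0-based continuous coordinates.

#' Shoelace area of one ring
#' @keywords internal
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Signed area-of-polygon with holes subtracted
#' @keywords internal
polygon_area <- function(poly) {
  a <- ring_area(poly$outer)
  if (length(poly$holes)) a <- a - sum(vapply(poly$holes, ring_area, numeric(1)))
  a
}

#' Even-odd point-in-ring test, vectorized over points
#' @param px,py point coordinates.
#' @keywords internal
points_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Even-odd point-in-polygon (holes excluded)
#' @keywords internal
points_in_polygon <- function(px, py, poly) {
  inside <- points_in_ring(px, py, poly$outer)
  for (h in poly$holes) inside <- inside & !points_in_ring(px, py, h)
  inside
}

#' Rasterize a set of polygons over a window by scanline even-odd filling
#'
#' A pixel is set to 1 iff its centre lies inside any polygon (outer ring,
#' minus holes). Coordinates are interpreted at the stated level: the caller
#' scales rings before rasterizing at levels > 0.
#'
#' @param polys list of polygons.
#' @param window c(x0, y0, x1, y1) 0-based half-open, in the same coordinate
#'   frame as the rings.
#' @return integer 0/1 matrix of shape (y1 - y0) x (x1 - x0).
#' @keywords internal
rasterize_polygons <- function(polys, window) {
  w <- as.integer(window[3] - window[1])
  h <- as.integer(window[4] - window[2])
  out <- matrix(0L, h, w)
  if (!length(polys)) return(out)
  xc <- window[1] + seq_len(w) - 0.5
  for (poly in polys) {
    rings <- c(list(poly$outer), poly$holes)
    ylim <- range(unlist(lapply(rings, function(r) r[, 2])))
    r0 <- max(1L, as.integer(floor(ylim[1] - window[2] + 0.5)) + 0L)
    r1 <- min(h, as.integer(ceiling(ylim[2] - window[2] + 0.5)))
    if (r1 < r0) next
    for (r in r0:r1) {
      yc <- window[2] + r - 0.5
      # even-odd crossings per ring, combined by xor across outer + holes
      inside <- rep(FALSE, w)
      for (ring in rings) {
        xs <- ring_scan_crossings(ring, yc)
        if (!length(xs)) next
        # pixel centre is inside after an odd number of crossings to its left
        cnt <- findInterval(xc, sort(xs))
        inside <- xor(inside, cnt %% 2L == 1L)
      }
      out[r, ] <- out[r, ] | inside
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' x-coordinates where a ring crosses the horizontal line y = yc
#' @keywords internal
ring_scan_crossings <- function(ring, yc) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  hit <- (y > yc) != (y[j] > yc)
  if (!any(hit)) return(numeric(0))
  i <- which(hit)
  x[j][i] + (yc - y[j][i]) / (y[i] - y[j][i]) * (x[i] - x[j][i])
}

#' Clip a ring to an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' @param ring n x 2 matrix.
#' @param rect c(x0, y0, x1, y1).
#' @return clipped ring (possibly with 0 rows).
#' @keywords internal
clip_ring_rect <- function(ring, rect) {
  clip_edge <- function(pts, keep, intersect) {
    if (!nrow(pts)) return(pts)
    n <- nrow(pts)
    out <- matrix(numeric(0), 0, 2)
    prev <- pts[n, ]
    prev_in <- keep(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; cur_in <- keep(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
      prev <- cur; prev_in <- cur_in
    }
    out
  }
  interp <- function(p, q, t) p + t * (q - p)
  ring <- clip_edge(ring, function(p) p[1] >= rect[1], function(p, q)
    interp(p, q, (rect[1] - p[1]) / (q[1] - p[1])))
  ring <- clip_edge(ring, function(p) p[1] <= rect[3], function(p, q)
    interp(p, q, (rect[3] - p[1]) / (q[1] - p[1])))
  ring <- clip_edge(ring, function(p) p[2] >= rect[2], function(p, q)
    interp(p, q, (rect[2] - p[2]) / (q[2] - p[2])))
  ring <- clip_edge(ring, function(p) p[2] <= rect[4], function(p, q)
    interp(p, q, (rect[4] - p[2]) / (q[2] - p[2])))
  ring
}

#' Regular-polygon approximation of a circle
#' @keywords internal
circle_ring <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}
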