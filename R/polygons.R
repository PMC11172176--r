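## Plain planar polygon primitives in micrometre coordinates.
##
## A *ring* is a list(x =, y =) of vertices without the closing duplicate;
## orientation is irrelevant (areas are absolute). A *multipolygon* is an
## unnamed list of rings representing a union of disjoint simple polygons
## (tumor nests never overlap by construction). There is no polygon-clipping
## dependency in this stack, so every downstream quantity is derived from
## three exact primitives: the shoelace area, an even-odd point-in-ring
## test, and the exact point-to-boundary distance.

#' Construct a polygon ring
#'
#' @param x,y Numeric vertex coordinates in micrometres, in order around the
#'   ring, without repeating the first vertex at the end (a closing duplicate
#'   is dropped if present).
#' @param validate Check that the ring is simple (no self-intersection)?
#' @return A list with elements `x` and `y`.
#' @export
polygon_ring <- function(x, y, validate = TRUE) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) >= 2 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]
    y <- y[-length(y)]
  }
  if (length(x) < 3) stop("a polygon ring needs at least 3 vertices")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("polygon vertices must be finite")
  ring <- list(x = as.numeric(x), y = as.numeric(y))
  if (validate && !is_simple_ring(ring))
    stop("polygon ring is self-intersecting")
  ring
}

#' Shoelace area of a single ring (micrometre^2, always non-negative)
#' @param ring A ring from [polygon_ring()].
#' @export
ring_area <- function(ring) {
  x <- ring$x
  y <- ring$y
  j <- c(seq_along(x)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Total area of a multipolygon (list of disjoint rings), in micrometre^2
#' @param mp List of rings (may be empty).
#' @export
multipolygon_area <- function(mp) {
  if (length(mp) == 0) return(0)
  sum(vapply(mp, ring_area, numeric(1)))
}

ring_bbox <- function(ring) {
  c(xmin = min(ring$x), xmax = max(ring$x),
    ymin = min(ring$y), ymax = max(ring$y))
}

multipolygon_bbox <- function(mp) {
  bb <- vapply(mp, ring_bbox, numeric(4))
  c(xmin = min(bb["xmin", ]), xmax = max(bb["xmax", ]),
    ymin = min(bb["ymin", ]), ymax = max(bb["ymax", ]))
}

ring_segments <- function(ring) {
  n <- length(ring$x)
  j <- c(seq_len(n)[-1], 1L)
  list(x0 = ring$x, y0 = ring$y, x1 = ring$x[j], y1 = ring$y[j])
}

#' Even-odd point-in-polygon test
#'
#' Points exactly on the boundary are not guaranteed a side by the crossing
#' test; compartment assignment resolves the boundary through the distance
#' (distance 0 means tumoral), so the ambiguity never surfaces.
#'
#' @param px,py Query point coordinates (vectors).
#' @param ring A single ring.
#' @return Logical vector.
#' @export
point_in_ring <- function(px, py, ring) {
  cpp_in_ring(as.numeric(px), as.numeric(py), ring$x, ring$y)
}

#' Point membership in a multipolygon (union of rings)
#' @param px,py Query point coordinates.
#' @param mp List of rings.
#' @export
point_in_multipolygon <- function(px, py, mp) {
  out <- rep(FALSE, length(px))
  for (ring in mp) {
    idx <- which(!out)
    if (length(idx) == 0) break
    out[idx] <- point_in_ring(px[idx], py[idx], ring)
  }
  out
}

#' Exact minimum distance from points to the boundary of a multipolygon
#'
#' Distance to the boundary only; use [distance_to_tumor()] for the signed
#' convention (0 inside).
#' @param px,py Query point coordinates.
#' @param mp List of rings.
#' @export
boundary_distance <- function(px, py, mp) {
  if (length(mp) == 0) stop("empty multipolygon has no boundary")
  d <- rep(Inf, length(px))
  for (ring in mp) {
    s <- ring_segments(ring)
    d <- pmin(d, cpp_min_seg_dist(as.numeric(px), as.numeric(py),
                                  s$x0, s$y0, s$x1, s$y1))
  }
  d
}

# O(n^2) proper-crossing test between non-adjacent edges; adequate for the
# ring sizes used here (<= a few hundred vertices).
is_simple_ring <- function(ring) {
  n <- length(ring$x)
  s <- ring_segments(ring)
  for (i in seq_len(n - 2L)) {
    js <- seq.int(i + 2L, n)
    if (i == 1L) js <- js[js != n]  # edges n and 1 are adjacent
    if (length(js) == 0) next
    if (any(segments_cross(s$x0[i], s$y0[i], s$x1[i], s$y1[i],
                           s$x0[js], s$y0[js], s$x1[js], s$y1[js])))
      return(FALSE)
  }
  TRUE
}

# Vectorized proper-intersection test of segment (ax0,ay0)-(ax1,ay1)
# against segments (bx0,by0)-(bx1,by1).
segments_cross <- function(ax0, ay0, ax1, ay1, bx0, by0, bx1, by1) {
  o <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  d1 <- o(ax0, ay0, ax1, ay1, bx0, by0)
  d2 <- o(ax0, ay0, ax1, ay1, bx1, by1)
  d3 <- o(bx0, by0, bx1, by1, ax0, ay0)
  d4 <- o(bx0, by0, bx1, by1, ax1, ay1)
  d1 * d2 < 0 & d3 * d4 < 0
}
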