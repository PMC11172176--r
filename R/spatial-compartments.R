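## Tumor/stroma compartment geometry.
##
## All coordinates are real-valued micrometres in the slide frame. The tumor
## nest is a multipolygon of disjoint simple rings inside the ROI polygon.
## The analyzed stroma is the peritumoral band: points of the ROI outside the
## tumor within `band_width` (default 50 um) of the tumor-nest boundary.
## Polygon boundaries are closed sets: a cell exactly on the tumor boundary
## has distance 0 and is tumoral.

#' Per-ROI region geometry
#'
#' @param case_id,roi_id Identifiers; geometry is keyed on (case, ROI) so the
#'   same placements apply to both markers of a case.
#' @param roi Ring delimiting the ROI (see [polygon_ring()]).
#' @param tumor List of rings (possibly empty) for the tumor-nest polygons;
#'   must lie inside the ROI.
#' @param roi_kind One of `"hotspot-stroma"`, `"hotspot-tumor"`,
#'   `"interface"`, `"synthetic"`.
#' @param validate Check ring simplicity and tumor-inside-ROI containment?
#' @return An object of class `region_geometry`.
#' @export
region_geometry <- function(case_id, roi_id, roi, tumor = list(),
                            roi_kind = "synthetic", validate = TRUE) {
  roi_kind <- match.arg(roi_kind,
    c("synthetic", "hotspot-stroma", "hotspot-tumor", "interface"))
  if (validate) {
    if (!is_simple_ring(roi)) stop("ROI polygon is self-intersecting")
    for (ring in tumor) {
      if (!is_simple_ring(ring)) stop("tumor polygon is self-intersecting")
      if (!all(point_in_ring(ring$x, ring$y, roi)))
        stop("tumor polygon extends outside the ROI")
    }
  }
  structure(
    list(case_id = as.character(case_id), roi_id = as.character(roi_id),
         roi = roi, tumor = tumor, roi_kind = roi_kind),
    class = "region_geometry")
}

#' @export
print.region_geometry <- function(x, ...) {
  cat(sprintf("<region_geometry> case %s ROI %s (%s): %d tumor nest(s), ROI area %.3f mm^2\n",
              x$case_id, x$roi_id, x$roi_kind, length(x$tumor),
              ring_area(x$roi) / 1e6))
  invisible(x)
}

#' Distance from points to the tumor nest
#'
#' 0 for points inside or on the boundary of any tumor polygon, otherwise the
#' exact minimum Euclidean distance to the tumor boundary. Distances are
#' within-ROI: only the tumor polygons of the supplied geometry are
#' considered.
#'
#' @param x,y Point coordinates in micrometres (vectors).
#' @param tumor Tumor multipolygon (list of rings) or a `region_geometry`.
#' @return Non-negative numeric vector of distances in micrometres.
#' @export
distance_to_tumor <- function(x, y, tumor) {
  if (inherits(tumor, "region_geometry")) tumor <- tumor$tumor
  if (length(tumor) == 0)
    stop("degenerate ROI: empty tumor multipolygon, distance undefined")
  d <- boundary_distance(x, y, tumor)
  d[point_in_multipolygon(x, y, tumor)] <- 0
  d
}

#' Build the peritumoral stromal band
#'
#' The band is the set of ROI points strictly outside the tumor nest and
#' within `band_width` of its boundary (Euclidean dilation minus the tumor,
#' intersected with the ROI). It is represented exactly through the distance
#' field rather than as an approximating buffer polygon: membership is
#' evaluated with [band_contains()] and the area by grid quadrature of the
#' exact distance over pixel centers at `resolution` micrometres.
#'
#' @param tumor Tumor multipolygon or `region_geometry`.
#' @param roi ROI ring (ignored when `tumor` is a `region_geometry`).
#' @param band_width Band width in micrometres (default 50).
#' @param resolution Quadrature grid step in micrometres (default 1).
#' @return An object of class `stromal_band` with the band area in `area_um2`
#'   and `area_mm2`.
#' @export
build_stromal_band <- function(tumor, roi = NULL, band_width = 50,
                               resolution = 1) {
  if (inherits(tumor, "region_geometry")) {
    roi <- tumor$roi
    tumor <- tumor$tumor
  }
  stopifnot(band_width > 0, resolution > 0)
  if (length(tumor) == 0)
    stop("degenerate ROI: empty tumor multipolygon, stromal band undefined")
  rb <- ring_bbox(roi)
  tb <- multipolygon_bbox(tumor)
  pad <- band_width + resolution
  xmin <- max(tb["xmin"] - pad, rb["xmin"])
  xmax <- min(tb["xmax"] + pad, rb["xmax"])
  ymin <- max(tb["ymin"] - pad, rb["ymin"])
  ymax <- min(tb["ymax"] + pad, rb["ymax"])
  gx <- seq(xmin + resolution / 2, xmax, by = resolution)
  gy <- seq(ymin + resolution / 2, ymax, by = resolution)
  nx <- length(gx)
  ny <- length(gy)
  # distance field evaluated per tumor ring over its padded window only
  dist <- matrix(Inf, nrow = nx, ncol = ny)
  intum <- matrix(FALSE, nrow = nx, ncol = ny)
  for (ring in tumor) {
    bb <- ring_bbox(ring)
    ix <- which(gx >= bb["xmin"] - pad & gx <= bb["xmax"] + pad)
    iy <- which(gy >= bb["ymin"] - pad & gy <= bb["ymax"] + pad)
    if (length(ix) == 0 || length(iy) == 0) next
    px <- rep(gx[ix], times = length(iy))
    py <- rep(gy[iy], each = length(ix))
    s <- ring_segments(ring)
    d <- cpp_min_seg_dist(px, py, s$x0, s$y0, s$x1, s$y1)
    inr <- cpp_in_ring(px, py, ring$x, ring$y)
    sub <- matrix(d, nrow = length(ix))
    dist[ix, iy] <- pmin(dist[ix, iy], sub)
    intum[ix, iy] <- intum[ix, iy] | matrix(inr, nrow = length(ix))
  }
  cand <- which(!intum & dist > 0 & dist <= band_width)
  n_band <- 0L
  if (length(cand)) {
    cx <- gx[(cand - 1L) %% nx + 1L]
    cy <- gy[(cand - 1L) %/% nx + 1L]
    n_band <- sum(point_in_ring(cx, cy, roi))
  }
  area_um2 <- n_band * resolution^2
  structure(
    list(tumor = tumor, roi = roi, band_width = band_width,
         resolution = resolution, area_um2 = area_um2,
         area_mm2 = area_um2 / 1e6),
    class = "stromal_band")
}

#' @export
print.stromal_band <- function(x, ...) {
  cat(sprintf("<stromal_band> width %g um, area %.4f mm^2 (grid %g um)\n",
              x$band_width, x$area_mm2, x$resolution))
  invisible(x)
}

#' Band membership predicate
#'
#' @param band A `stromal_band`.
#' @param x,y Point coordinates in micrometres.
#' @return Logical: inside the ROI, strictly outside the tumor, and within
#'   `band_width` of the tumor boundary.
#' @export
band_contains <- function(band, x, y) {
  d <- distance_to_tumor(x, y, band$tumor)
  point_in_ring(x, y, band$roi) & d > 0 & d <= band$band_width
}

#' Assign detected cells to compartments
#'
#' Adds `distance_to_tumor` (micrometres) and `compartment`
#' (`tumor`/`stroma`/`excluded`) columns. Tumoral means distance 0; stromal
#' means inside the ROI with 0 < distance <= `band_width`; everything else
#' (beyond the band or outside the ROI polygon) is excluded.
#'
#' @param cells Data frame with `x_um`, `y_um` columns.
#' @param geom A `region_geometry`.
#' @param band_width Band width in micrometres (default 50).
#' @return `cells` with the two columns appended.
#' @export
assign_compartment <- function(cells, geom, band_width = 50) {
  stopifnot(inherits(geom, "region_geometry"),
            all(c("x_um", "y_um") %in% names(cells)))
  if (length(geom$tumor) == 0)
    stop("degenerate ROI: empty tumor multipolygon; exclude this ROI")
  n <- nrow(cells)
  if (n == 0) {
    cells$distance_to_tumor <- numeric(0)
    cells$compartment <- character(0)
    return(cells)
  }
  d <- distance_to_tumor(cells$x_um, cells$y_um, geom$tumor)
  in_roi <- point_in_ring(cells$x_um, cells$y_um, geom$roi) | d == 0
  if (any(!in_roi))
    warning(sprintf("%d cell(s) outside the ROI polygon were excluded",
                    sum(!in_roi)))
  comp <- rep("excluded", n)
  comp[in_roi & d == 0] <- "tumor"
  comp[in_roi & d > 0 & d <= band_width] <- "stroma"
  cells$distance_to_tumor <- d
  cells$compartment <- comp
  cells
}

#' Tumor and stromal-band areas of an ROI, in mm^2
#'
#' The tumor area is the exact shoelace area of the nest polygons; the
#' stromal area is the quadrature area of the peritumoral band. An ROI with
#' no tumor polygon is degenerate: the band is undefined and the stromal
#' area is returned as `NA` with a warning.
#'
#' @param geom A `region_geometry`.
#' @param band_width Band width in micrometres (default 50).
#' @param resolution Quadrature grid step in micrometres (default 1).
#' @return List with `tumor_area` and `stromal_area` (mm^2).
#' @export
region_areas <- function(geom, band_width = 50, resolution = 1) {
  stopifnot(inherits(geom, "region_geometry"))
  tumor_area <- multipolygon_area(geom$tumor) / 1e6
  if (length(geom$tumor) == 0) {
    warning(sprintf("ROI %s/%s has no tumor polygon: stromal band undefined",
                    geom$case_id, geom$roi_id))
    return(list(tumor_area = 0, stromal_area = NA_real_))
  }
  band <- build_stromal_band(geom$tumor, geom$roi, band_width, resolution)
  list(tumor_area = tumor_area, stromal_area = band$area_mm2)
}

#' Automatic hotspot window placement
#'
#' Deterministic stand-in for the manual low-power hotspot selection:
#' maximizes the number of supplied detections in a square window of
#' `window_area` mm^2 over a regular grid of candidate placements. Ties are
#' broken by the smallest x, then smallest y, origin. Callers filter the
#' detections to the marker (and compartment) of interest beforehand.
#'
#' @param cells Data frame with `x_um`, `y_um` of the candidate detections.
#' @param window_area Window area in mm^2 (default 1.96).
#' @param grid_step Grid spacing in micrometres (default: window side / 8).
#' @return List with the window `x`, `y` origin, `side` (um) and `count`.
#' @export
find_hotspots <- function(cells, window_area = 1.96, grid_step = NULL) {
  if (nrow(cells) == 0) stop("no detections supplied to hotspot search")
  side <- sqrt(window_area * 1e6)
  if (is.null(grid_step)) grid_step <- side / 8
  x0 <- seq(min(cells$x_um) - side, max(cells$x_um), by = grid_step)
  y0 <- seq(min(cells$y_um) - side, max(cells$y_um), by = grid_step)
  wx <- rep(x0, times = length(y0))
  wy <- rep(y0, each = length(x0))
  counts <- cpp_window_counts(cells$x_um, cells$y_um, wx, wy, side)
  best <- which(counts == max(counts))
  # tie-break: smallest x, then smallest y
  best <- best[order(wx[best], wy[best])][1]
  list(x = wx[best], y = wy[best], side = side, count = counts[best])
}
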