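## Plain-text interchange: cells.csv, regions.geojson (micrometre
## coordinates; feature properties case_id, roi_id, role), clinical.csv,
## survival.csv, flat key=value config files, and a small stable hash used
## by the run manifest.

#' Write / read a cell detection table
#'
#' Columns: case_id, roi_id, marker, x_um, y_um (plus any compartment
#' columns already present).
#' @param cells Data frame.
#' @param path CSV path.
#' @export
write_cells_csv <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write region geometries to GeoJSON
#'
#' One Feature per ROI boundary (`role = "roi"`) and per tumor-nest polygon
#' (`role = "tumor"`), with `case_id`/`roi_id` properties; coordinates in
#' micrometres.
#' @param geometries List of [region_geometry()] objects.
#' @param path Output path.
#' @export
write_regions_geojson <- function(geometries, path) {
  close_ring <- function(ring) {
    lapply(c(seq_along(ring$x), 1L), function(i) c(ring$x[i], ring$y[i]))
  }
  features <- list()
  for (g in geometries) {
    features[[length(features) + 1L]] <- list(
      type = "Feature",
      properties = list(case_id = g$case_id, roi_id = g$roi_id,
                        role = "roi", roi_kind = g$roi_kind),
      geometry = list(type = "Polygon",
                      coordinates = list(close_ring(g$roi))))
    for (ring in g$tumor) {
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        properties = list(case_id = g$case_id, roi_id = g$roi_id,
                          role = "tumor"),
        geometry = list(type = "Polygon",
                        coordinates = list(close_ring(ring))))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read region geometries from GeoJSON
#'
#' @param path GeoJSON path written by [write_regions_geojson()] (or any
#'   FeatureCollection of Polygon features with the same properties).
#' @return Named list of [region_geometry()] objects keyed `case_id/roi_id`.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop(sprintf("%s: not a GeoJSON FeatureCollection", path))
  rois <- list()
  tumors <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    props <- f$properties
    if (is.null(props$case_id) || is.null(props$roi_id) ||
        is.null(props$role))
      stop(sprintf("%s: feature %d lacks case_id/roi_id/role properties",
                   path, i))
    if (is.null(f$geometry) || f$geometry$type != "Polygon")
      stop(sprintf("%s: feature %d is not a Polygon", path, i))
    coords <- f$geometry$coordinates[[1]]
    ring <- polygon_ring(vapply(coords, function(p) as.numeric(p[[1]]),
                                numeric(1)),
                         vapply(coords, function(p) as.numeric(p[[2]]),
                                numeric(1)),
                         validate = FALSE)
    key <- paste(props$case_id, props$roi_id, sep = "/")
    if (props$role == "roi") {
      rois[[key]] <- list(ring = ring, case_id = props$case_id,
                          roi_id = props$roi_id,
                          roi_kind = props$roi_kind %||% "synthetic")
    } else {
      tumors[[key]] <- c(tumors[[key]], list(ring))
    }
  }
  out <- list()
  for (key in names(rois)) {
    r <- rois[[key]]
    out[[key]] <- region_geometry(r$case_id, r$roi_id, r$ring,
                                  tumors[[key]] %||% list(),
                                  roi_kind = r$roi_kind, validate = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a flat key=value configuration file
#' @param config Named list of scalar values.
#' @param path File path.
#' @export
write_config_file <- function(config, path) {
  keep <- vapply(config, function(v) is.atomic(v) && length(v) == 1,
                 logical(1))
  lines <- sprintf("%s=%s", names(config)[keep],
                   vapply(config[keep], as.character, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config_file
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(p) {
    v <- paste(p[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

# FNV-1a hash of a deparsed R object; stable fingerprint for run manifests.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483648), ch)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}
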