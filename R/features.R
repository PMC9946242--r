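#' Vector features as tidy tables
#'
#' Roads, rivers, lakes and sea-ice polygons enter the pipeline as a features
#' tibble: one row per feature with an `id`, a geometry `type`
#' (`"LineString"` or `"Polygon"`), a `coords` list-column holding an n x 2
#' coordinate matrix (the exterior ring for polygons, closed or not), and any
#' per-feature properties (e.g. `area_ha` for lakes, `flow_m3s` for rivers)
#' as ordinary columns. `features_tbl()` builds one from raw pieces;
#' `read_geojson_features()` parses a GeoJSON FeatureCollection into the same
#' shape (MultiLineString features are exploded into one row per part).
#'
#' @param coords A coordinate matrix or list of coordinate matrices.
#' @param type `"LineString"` or `"Polygon"`, recycled.
#' @param ... Further per-feature property vectors, recycled.
#' @return A tibble with columns `id`, `type`, `coords`, and properties.
#' @export
features_tbl <- function(coords, type = "LineString", ...) {
  if (is.matrix(coords)) coords <- list(coords)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2L) stop("coordinates must be two-column", call. = FALSE)
    storage.mode(m) <- "double"
    m
  })
  tibble::tibble(id = seq_along(coords),
                 type = rep_len(type, length(coords)),
                 coords = coords, ...)
}

#' @rdname features_tbl
#' @param path Path to a GeoJSON file.
#' @export
read_geojson_features <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  rows <- list()
  for (f in gj$features) {
    geom <- f$geometry
    props <- f$properties %||% list()
    mats <- switch(geom$type,
      LineString = list(coord_matrix(geom$coordinates)),
      MultiLineString = lapply(geom$coordinates, coord_matrix),
      Polygon = list(coord_matrix(geom$coordinates[[1]])),
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    type <- if (geom$type == "Polygon") "Polygon" else "LineString"
    for (m in mats) rows[[length(rows) + 1L]] <- c(list(type = type, coords = list(m)), props)
  }
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  dplyr::bind_cols(tibble::tibble(id = seq_len(nrow(out))), out)
}

coord_matrix <- function(x) {
  do.call(rbind, lapply(x, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
}

#' Cells traversed by a polyline ("any touch")
#'
#' Exact grid traversal: every cell whose interior or boundary the segment
#' chain passes through is returned. Thin linear features (roads, rivers,
#' railways) must not vanish at coarse resolution, so rasterization of lines
#' is any-touch rather than center-intersection.
#'
#' @param raster Template raster defining the grid.
#' @param coords n x 2 coordinate matrix of the polyline vertices.
#' @return Integer matrix with columns `row`, `col` (unique cells).
#' @keywords internal
line_cells <- function(raster, coords) {
  cs <- raster$cell_size; x0 <- raster$origin[1]; y0 <- raster$origin[2]
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  hits <- list()
  for (s in seq_len(nrow(coords) - 1L)) {
    p <- coords[s, ]; q <- coords[s + 1L, ]
    dx <- q[1] - p[1]; dy <- q[2] - p[2]
    # parameter values where the segment crosses grid lines
    ts <- c(0, 1)
    if (dx != 0) {
      k0 <- ceiling((min(p[1], q[1]) - x0) / cs)
      k1 <- floor((max(p[1], q[1]) - x0) / cs)
      if (k0 <= k1) ts <- c(ts, ((x0 + (k0:k1) * cs) - p[1]) / dx)
    }
    if (dy != 0) {
      k0 <- ceiling((min(p[2], q[2]) - y0) / cs)
      k1 <- floor((max(p[2], q[2]) - y0) / cs)
      if (k0 <= k1) ts <- c(ts, ((y0 + (k0:k1) * cs) - p[2]) / dy)
    }
    ts <- sort(unique(pmin(1, pmax(0, ts))))
    if (length(ts) < 2L) ts <- c(0, 1)
    mid <- (ts[-length(ts)] + ts[-1]) / 2
    mx <- p[1] + mid * dx; my <- p[2] + mid * dy
    cells <- cells_at(raster, mx, my)
    hits[[s]] <- cells[!is.na(cells$row), , drop = FALSE]
  }
  out <- unique(dplyr::bind_rows(hits))
  as.matrix(out)
}

#' Cells whose centers fall inside a polygon
#' @inheritParams line_cells
#' @keywords internal
polygon_cells <- function(raster, coords) {
  cen <- cell_centers(raster)
  inside <- pracma::inpolygon(cen$x, cen$y, coords[, 1], coords[, 2],
                              boundary = TRUE)
  as.matrix(cen[inside, c("row", "col")])
}
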