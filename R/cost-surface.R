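#' Resample a layer onto a target grid
#'
#' Aligns an input layer with the analysis grid (e.g., 300 m resolution).
#' Category layers are resampled by `"nearest"` neighbour or block `"mode"`
#' only — categories are never interpolated. Continuous rasters use
#' `"nearest"`. Target cells whose lookup falls outside the source extent
#' become `NA`.
#'
#' @param layer An `omc_raster` to resample.
#' @param target Template raster defining the output grid.
#' @param method `"nearest"` or `"mode"`. `"mode"` takes the modal category
#'   of the source cells whose centers fall in each target cell, ties broken
#'   by the lowest category code.
#' @return A raster of the same flavour as `layer`, on `target`'s grid.
#' @export
resample_layer <- function(layer, target, method = c("nearest", "mode")) {
  method <- match.arg(method)
  if (method == "mode" && !inherits(layer, "omc_category_raster")) {
    stop("`mode` resampling is only defined for category layers", call. = FALSE)
  }
  if (same_grid(layer, target)) return(layer)
  if (!extents_overlap(layer, target)) {
    stop("layer and target grids do not overlap", call. = FALSE)
  }
  nr <- nrow(target$values); nc <- ncol(target$values)
  out <- matrix(NA_real_, nr, nc)
  if (method == "nearest") {
    cen <- cell_centers(target)
    src <- cells_at(layer, cen$x, cen$y)
    ok <- !is.na(src$row)
    out[cbind(cen$row[ok], cen$col[ok])] <-
      layer$values[cbind(src$row[ok], src$col[ok])]
  } else {
    cen <- cell_centers(layer)
    tgt <- cells_at(target, cen$x, cen$y)
    ok <- !is.na(tgt$row) & !is.na(as.vector(layer$values))
    grp <- split(as.vector(layer$values)[ok],
                 (tgt$col[ok] - 1L) * nr + tgt$row[ok])
    idx <- as.integer(names(grp))
    out[idx] <- vapply(grp, cell_mode, numeric(1))
  }
  rebuild_raster(layer, out, target)
}

cell_mode <- function(v) {
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])  # which.max: first max = lowest code
}

extents_overlap <- function(a, b) {
  ax <- a$origin[1] + c(0, ncol(a$values)) * a$cell_size
  bx <- b$origin[1] + c(0, ncol(b$values)) * b$cell_size
  ay <- a$origin[2] - c(nrow(a$values), 0) * a$cell_size
  by <- b$origin[2] - c(nrow(b$values), 0) * b$cell_size
  ax[1] < bx[2] && bx[1] < ax[2] && ay[1] < by[2] && by[1] < ay[2]
}

rebuild_raster <- function(template, values, grid) {
  if (inherits(template, "omc_category_raster")) {
    category_raster(values, template$categories, grid$cell_size, grid$origin)
  } else if (inherits(template, "omc_current_map")) {
    current_map(values, grid$cell_size, grid$origin)
  } else if (inherits(template, "omc_cost_raster")) {
    cost_raster(values, grid$cell_size, grid$origin)
  } else {
    new_omc_raster(values, grid$cell_size, grid$origin, class(template)[1])
  }
}

#' Rasterize vector features into a category layer
#'
#' Burns features onto the grid at a single schema category. Polylines are
#' rasterized any-touch (every cell the line passes through); polygons by the
#' center-intersection rule (cells whose centers fall inside, boundary
#' inclusive). An empty feature set yields an all-nodata layer, which is a
#' valid input to [combine_layers()].
#'
#' @param features A features tibble (see [features_tbl()]); may be filtered
#'   beforehand (e.g., lakes above an area threshold).
#' @param grid Template raster defining the output grid.
#' @param category Category label (resolved against `schema`) or integer code.
#' @param schema Cost schema used to resolve `category` labels.
#' @return An `omc_category_raster` with the category where features touch,
#'   `NA` elsewhere.
#' @export
rasterize_features <- function(features, grid, category,
                               schema = cost_schema()) {
  code <- if (is.character(category)) schema_code(schema, category) else as.integer(category)
  out <- matrix(NA_integer_, nrow(grid$values), ncol(grid$values))
  if (!is.null(features) && nrow(features) > 0L) {
    for (i in seq_len(nrow(features))) {
      cells <- if (features$type[i] == "Polygon") {
        polygon_cells(grid, features$coords[[i]])
      } else {
        line_cells(grid, features$coords[[i]])
      }
      if (nrow(cells)) out[cells] <- code
    }
  }
  category_raster(out, schema$codes, grid$cell_size, grid$origin)
}

#' Natural-feature cost thresholds
#'
#' Cutoffs above which natural features are treated as movement barriers:
#' elevation above 2300 m, slopes above 30 degrees, lakes of at least 10 ha
#' and rivers flowing more than 28 m^3/s are assigned the high cost;
#' permanent sea ice gets a medium-low cost because some mammals travel
#' across it between Arctic islands. Comparison operators follow those
#' conventions exactly: strict for elevation, slope and flow, non-strict for
#' lake area.
#'
#' @param elevation_cutoff Elevation cutoff, m.
#' @param slope_cutoff Slope cutoff, degrees.
#' @param lake_min_area Minimum lake area, ha (inclusive).
#' @param river_min_flow Minimum river flow, m^3/s (exclusive).
#' @param sea_ice_category Category label assigned to sea ice.
#' @return A list of thresholds, class `omc_thresholds`.
#' @export
natural_thresholds <- function(elevation_cutoff = 2300, slope_cutoff = 30,
                               lake_min_area = 10, river_min_flow = 28,
                               sea_ice_category = "medium_low") {
  vals <- c(elevation_cutoff, slope_cutoff, lake_min_area, river_min_flow)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all cutoffs must be positive", call. = FALSE)
  }
  structure(list(elevation_cutoff = elevation_cutoff,
                 slope_cutoff = slope_cutoff,
                 lake_min_area = lake_min_area,
                 river_min_flow = river_min_flow,
                 sea_ice_category = sea_ice_category),
            class = "omc_thresholds")
}

#' Build category layers from natural features
#'
#' Applies [natural_thresholds()] to elevation and slope rasters and to lake,
#' river and sea-ice vector layers, returning one category layer per rule,
#' ready for [combine_layers()]. Any layer passed as `NULL` has its rule
#' skipped with a warning.
#'
#' @param grid Template raster defining the analysis grid.
#' @param elevation,slope Continuous rasters aligned to `grid`, or `NULL`.
#' @param lakes Polygon features tibble with an `area_ha` column, or `NULL`.
#' @param rivers Polyline features tibble with a `flow_m3s` column, or `NULL`.
#' @param sea_ice Polygon features tibble, or `NULL`.
#' @param thresholds An `omc_thresholds`.
#' @param schema Cost schema supplying the category codes.
#' @return Named list of `omc_category_raster` layers.
#' @export
apply_natural_thresholds <- function(grid, elevation = NULL, slope = NULL,
                                     lakes = NULL, rivers = NULL,
                                     sea_ice = NULL,
                                     thresholds = natural_thresholds(),
                                     schema = cost_schema()) {
  high <- schema_code(schema, schema$categories[length(schema$categories)])
  layers <- list()
  threshold_layer <- function(r, cutoff) {
    m <- matrix(NA_integer_, nrow(grid$values), ncol(grid$values))
    m[!is.na(r$values) & r$values > cutoff] <- high
    category_raster(m, schema$codes, grid$cell_size, grid$origin)
  }
  if (is.null(elevation)) warning("no elevation layer; rule skipped") else {
    stopifnot(same_grid(elevation, grid))
    layers$elevation <- threshold_layer(elevation, thresholds$elevation_cutoff)
  }
  if (is.null(slope)) warning("no slope layer; rule skipped") else {
    stopifnot(same_grid(slope, grid))
    layers$slope <- threshold_layer(slope, thresholds$slope_cutoff)
  }
  if (is.null(lakes)) warning("no lakes layer; rule skipped") else {
    big <- lakes[lakes$area_ha >= thresholds$lake_min_area, , drop = FALSE]
    layers$lakes <- rasterize_features(big, grid, high, schema)
  }
  if (is.null(rivers)) warning("no rivers layer; rule skipped") else {
    big <- rivers[rivers$flow_m3s > thresholds$river_min_flow, , drop = FALSE]
    layers$rivers <- rasterize_features(big, grid, high, schema)
  }
  if (is.null(sea_ice)) warning("no sea-ice layer; rule skipped") else {
    layers$sea_ice <- rasterize_features(sea_ice, grid,
                                         thresholds$sea_ice_category, schema)
  }
  layers
}

#' Combine category layers into a movement-cost raster
#'
#' The single-surface combination rule: each cell takes the cost of the
#' highest-ranked category present in any layer ("highest cost wins"); cells
#' covered by no layer are assigned the schema's low cost, so the output has
#' no nodata. Combination is order-invariant and monotone — adding a layer
#' can never lower a cell's cost.
#'
#' @param layers A list of `omc_category_raster` objects on a common grid
#'   (or a single raster).
#' @param schema Cost schema mapping category ranks to cost values.
#' @return An `omc_cost_raster`.
#' @examples
#' g <- category_raster(matrix(c(NA, 2L, 4L, NA), 2), 1:4)
#' combine_layers(list(g), cost_schema())
#' @export
combine_layers <- function(layers, schema = cost_schema()) {
  if (inherits(layers, "omc_raster")) layers <- list(layers)
  if (length(layers) < 1L) stop("need at least one layer", call. = FALSE)
  ref <- layers[[1]]
  rank <- matrix(0L, nrow(ref$values), ncol(ref$values))
  for (l in layers) {
    if (!inherits(l, "omc_category_raster")) {
      stop("layers must be category rasters", call. = FALSE)
    }
    if (!same_grid(l, ref)) stop("layers are on misaligned grids", call. = FALSE)
    v <- l$values
    v[is.na(v)] <- 0L
    rank <- pmax(rank, v)
  }
  rank[rank == 0L] <- 1L  # uncovered cells get the low category
  cost_raster(matrix(schema_cost(schema, rank), nrow(rank)),
              ref$cell_size, ref$origin)
}

#' Re-express a cost raster as a category layer
#'
#' Inverse of [combine_layers()] for rasters whose values all belong to the
#' schema's cost set; used to check idempotence of the combination rule and
#' to feed a combined surface back through scenario machinery.
#'
#' @param cost An `omc_cost_raster` whose values are all schema costs.
#' @param schema The schema to invert against.
#' @return An `omc_category_raster`.
#' @export
cost_to_categories <- function(cost, schema = cost_schema()) {
  code <- match(cost$values, schema$costs)
  if (anyNA(code[!is.na(cost$values)])) {
    stop("raster contains costs outside the schema", call. = FALSE)
  }
  category_raster(matrix(as.integer(code), nrow(cost$values)),
                  schema$codes, cost$cell_size, cost$origin)
}
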