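#' Crop a raster to a row/column window
#'
#' @param raster An `omc_raster`.
#' @param rows,cols Integer ranges (1-based, inclusive).
#' @return A raster of the same flavour with adjusted origin.
#' @export
crop_raster <- function(raster, rows, cols) {
  rows <- range(rows); cols <- range(cols)
  vals <- raster$values[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  origin <- c(raster$origin[1] + (cols[1] - 1) * raster$cell_size,
              raster$origin[2] - (rows[1] - 1) * raster$cell_size)
  rebuild_raster(raster, vals,
                 list(cell_size = raster$cell_size, origin = origin))
}

#' Build a buffered tiling scheme
#'
#' Splits a grid into row-major rectangular tiles (the last row/column of
#' tiles may be smaller) and attaches to each tile a buffered analysis
#' window: the tile grown on every side by a buffer equal to
#' `buffer_fraction` of the mean of the tile's height and width, rounded to
#' whole cells and clipped at the raster edge. The default 20% buffer damps
#' the influence of artificial strip placement at tile borders on the
#' interior current pattern.
#'
#' @param grid Template raster (or `c(nrows, ncols)`).
#' @param tile_rows,tile_cols Tile height and width in cells.
#' @param buffer_fraction Buffer width as a fraction of mean tile side.
#' @return An `omc_tile_scheme`: a tibble with core extents
#'   (`row_start`..`col_end`), buffer width, and buffered window extents
#'   (`brow_start`..`bcol_end`), plus the grid dimensions as attributes.
#' @examples
#' make_tiles(c(100, 100), 50, 50)  # 4 tiles, 10-cell buffers
#' @export
make_tiles <- function(grid, tile_rows, tile_cols, buffer_fraction = 0.20) {
  dims <- if (inherits(grid, "omc_raster")) dim(grid$values) else as.integer(grid)
  if (tile_rows < 1 || tile_cols < 1) {
    stop("tile dimensions must be positive", call. = FALSE)
  }
  if (tile_rows > dims[1] || tile_cols > dims[2]) {
    stop("tile dimensions exceed the grid", call. = FALSE)
  }
  if (buffer_fraction < 0) stop("buffer_fraction must be >= 0", call. = FALSE)
  row0 <- seq(1L, dims[1], by = tile_rows)
  col0 <- seq(1L, dims[2], by = tile_cols)
  scheme <- tidyr::expand_grid(row_start = row0, col_start = col0)
  scheme <- dplyr::mutate(scheme,
    row_end = pmin(.data$row_start + tile_rows - 1L, dims[1]),
    col_end = pmin(.data$col_start + tile_cols - 1L, dims[2]),
    buffer = as.integer(round(buffer_fraction *
      ((.data$row_end - .data$row_start + 1) +
       (.data$col_end - .data$col_start + 1)) / 2)),
    brow_start = pmax(1L, .data$row_start - .data$buffer),
    brow_end = pmin(dims[1], .data$row_end + .data$buffer),
    bcol_start = pmax(1L, .data$col_start - .data$buffer),
    bcol_end = pmin(dims[2], .data$col_end + .data$buffer),
    tile_id = dplyr::row_number(), .before = 1
  )
  structure(scheme, class = c("omc_tile_scheme", class(scheme)),
            dims = dims, buffer_fraction = buffer_fraction)
}

#' Run the omnidirectional analysis tile by tile
#'
#' Runs [omnidirectional_current()] on each tile's buffered window, then
#' crops the buffer off, returning one map per core tile. A tile whose solve
#' fails is reported by id (with a warning) and returned as `NULL`; the run
#' continues.
#'
#' @param cost The full `omc_cost_raster` the scheme was built on.
#' @param scheme An `omc_tile_scheme`.
#' @param ... Passed to [omnidirectional_current()].
#' @return A list of `omc_current_map` (or `NULL`), one per tile.
#' @export
run_tiles <- function(cost, scheme, ...) {
  dims <- attr(scheme, "dims")
  if (!all(dims == dim(cost$values))) {
    stop("scheme was built for a different grid", call. = FALSE)
  }
  lapply(seq_len(nrow(scheme)), function(k) {
    t <- scheme[k, ]
    res <- tryCatch({
      win <- crop_raster(cost, c(t$brow_start, t$brow_end),
                         c(t$bcol_start, t$bcol_end))
      omni <- omnidirectional_current(win, ...)
      crop_raster(omni,
                  c(t$row_start, t$row_end) - t$brow_start + 1L,
                  c(t$col_start, t$col_end) - t$bcol_start + 1L)
    }, error = function(e) {
      warning(sprintf("tile %d failed: %s", t$tile_id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    res
  })
}

#' Stitch per-tile maps into one map
#'
#' Copies non-overlapping cells and averages cells covered by several tiles
#' (the mean-of-overlap rule). Any grid cell covered by no tile is an error
#' reported with its coordinates.
#'
#' @param maps List of per-tile `omc_current_map`s from [run_tiles()].
#' @param scheme The `omc_tile_scheme` the maps were produced under.
#' @return An `omc_current_map` covering the whole grid.
#' @export
stitch <- function(maps, scheme) {
  dims <- attr(scheme, "dims")
  acc <- matrix(0, dims[1], dims[2])
  cnt <- matrix(0L, dims[1], dims[2])
  cs <- NULL; orig <- NULL
  for (k in seq_len(nrow(scheme))) {
    m <- maps[[k]]
    if (is.null(m)) next
    t <- scheme[k, ]
    rows <- t$row_start:t$row_end; cols <- t$col_start:t$col_end
    v <- m$values
    ok <- !is.na(v)
    acc[rows, cols][ok] <- acc[rows, cols][ok] + v[ok]
    cnt[rows, cols][ok] <- cnt[rows, cols][ok] + 1L
    if (is.null(cs)) {
      cs <- m$cell_size
      orig <- c(m$origin[1] - (t$col_start - 1) * cs,
                m$origin[2] + (t$row_start - 1) * cs)
    }
  }
  if (any(cnt == 0L)) {
    gap <- which(cnt == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("coverage gap at cell (%d, %d)", gap[1], gap[2]),
         call. = FALSE)
  }
  current_map(acc / cnt, cs, orig)
}

#' Repair stitching seams with extra centred tiles
#'
#' Reruns the omnidirectional analysis on buffered tiles centred over seam
#' artefacts, then takes the cell-wise mean of the stitched map and every
#' seam-tile map where it covers. With an empty seam list the stitched map
#' is returned unchanged.
#'
#' @param cost The full `omc_cost_raster`.
#' @param stitched The stitched `omc_current_map`.
#' @param seam_tiles A tibble/data frame with columns `row_start`, `row_end`,
#'   `col_start`, `col_end` (one row per repair tile), or `NULL`/empty.
#' @param buffer_fraction Buffer applied to each seam tile.
#' @param ... Passed to [omnidirectional_current()].
#' @return An `omc_current_map`.
#' @export
seam_repair <- function(cost, stitched, seam_tiles, buffer_fraction = 0.20,
                        ...) {
  if (is.null(seam_tiles) || nrow(seam_tiles) == 0L) return(stitched)
  dims <- dim(cost$values)
  acc <- stitched$values
  cnt <- matrix(1L, dims[1], dims[2])
  for (k in seq_len(nrow(seam_tiles))) {
    t <- seam_tiles[k, ]
    if (t$row_start < 1 || t$row_end > dims[1] ||
        t$col_start < 1 || t$col_end > dims[2]) {
      stop("seam tile ", k, " falls outside the grid", call. = FALSE)
    }
    buf <- as.integer(round(buffer_fraction *
      ((t$row_end - t$row_start + 1) + (t$col_end - t$col_start + 1)) / 2))
    win <- crop_raster(cost,
                       c(max(1, t$row_start - buf), min(dims[1], t$row_end + buf)),
                       c(max(1, t$col_start - buf), min(dims[2], t$col_end + buf)))
    omni <- omnidirectional_current(win, ...)
    core <- crop_raster(omni,
                        c(t$row_start, t$row_end) - max(1, t$row_start - buf) + 1L,
                        c(t$col_start, t$col_end) - max(1, t$col_start - buf) + 1L)
    rows <- t$row_start:t$row_end; cols <- t$col_start:t$col_end
    ok <- !is.na(core$values)
    acc[rows, cols][ok] <- acc[rows, cols][ok] + core$values[ok]
    cnt[rows, cols][ok] <- cnt[rows, cols][ok] + 1L
  }
  current_map(acc / cnt, stitched$cell_size, stitched$origin)
}

#' Flag suspicious seams in a stitched map
#'
#' A screening statistic (not part of the original protocol, where seams
#' were judged by eye): every internal tile boundary whose mean absolute
#' cross-boundary difference exceeds `factor` times the landscape-wide mean
#' absolute orthogonal-neighbour difference is flagged.
#'
#' @param map A stitched `omc_current_map`.
#' @param scheme The tiling scheme that produced it.
#' @param factor Flagging multiplier.
#' @return A tibble: `kind` (`"row"`/`"col"` boundary), `index` (boundary
#'   after this row/col), `score` (ratio to the landscape mean), `flagged`.
#' @export
detect_seams <- function(map, scheme, factor = 3) {
  v <- map$values
  base <- mean(c(abs(diff(v)), abs(t(diff(t(v))))), na.rm = TRUE)
  row_b <- setdiff(unique(scheme$row_end), nrow(v))
  col_b <- setdiff(unique(scheme$col_end), ncol(v))
  out <- dplyr::bind_rows(
    tibble::tibble(kind = "row", index = row_b,
                   score = vapply(row_b, function(r)
                     mean(abs(v[r, ] - v[r + 1, ]), na.rm = TRUE) / base,
                     numeric(1))),
    tibble::tibble(kind = "col", index = col_b,
                   score = vapply(col_b, function(cc)
                     mean(abs(v[, cc] - v[, cc + 1]), na.rm = TRUE) / base,
                     numeric(1)))
  )
  dplyr::mutate(out, flagged = .data$score > factor)
}

#' Serialize a tile scheme to JSON (and back)
#'
#' @param scheme An `omc_tile_scheme`.
#' @param path File path.
#' @export
write_tile_scheme <- function(scheme, path) {
  jsonlite::write_json(list(dims = attr(scheme, "dims"),
                            buffer_fraction = attr(scheme, "buffer_fraction"),
                            tiles = as.data.frame(scheme)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tile_scheme
#' @export
read_tile_scheme <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(tibble::as_tibble(spec$tiles),
            class = c("omc_tile_scheme", class(tibble::tibble())),
            dims = as.integer(spec$dims),
            buffer_fraction = spec$buffer_fraction)
}
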