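#' Grid-registered raster objects
#'
#' `omnicurrent` works on lightweight matrix-backed rasters. A raster is a
#' numeric or integer matrix plus a square cell size and the map coordinates
#' of the top-left *outer* corner of the grid. Rows run north to south (row 1
#' is the northern edge), columns west to east, and cell extents are half-open
#' so every point falls in exactly one cell. Three flavours share the layout:
#'
#' * `cost_raster()` — strictly positive, finite movement costs. `NA` cells
#'   are allowed and treated as masked (e.g., ocean); the circuit solver
#'   excludes them.
#' * `category_raster()` — integer cost-category codes drawn from a
#'   [cost_schema()] category set, `NA` = nodata.
#' * `current_map()` — nonnegative current density, produced by the solver.
#'
#' @param values A matrix (numeric for costs/currents, integer codes for
#'   categories). Row 1 is the northern row.
#' @param cell_size Edge length of a (square) cell in map units.
#' @param origin Length-2 numeric, `c(x, y)` of the top-left pixel's outer
#'   corner.
#' @param categories Integer vector of admissible category codes.
#' @return An object of class `omc_raster` (subclassed as `omc_cost_raster`,
#'   `omc_category_raster` or `omc_current_map`).
#' @examples
#' r <- cost_raster(matrix(1, 4, 5))
#' dim(r)
#' @name omc_raster
NULL

new_omc_raster <- function(values, cell_size, origin, subclass) {
  if (!is.matrix(values) || nrow(values) < 1L || ncol(values) < 1L) {
    stop("`values` must be a matrix with at least one row and one column",
         call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("`origin` must be c(x, y)", call. = FALSE)
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = c(subclass, "omc_raster")
  )
}

#' @rdname omc_raster
#' @export
cost_raster <- function(values, cell_size = 1, origin = c(0, 0)) {
  values <- as_value_matrix(values)
  ok <- values[!is.na(values)]
  if (length(ok) == 0L) stop("cost raster is entirely masked", call. = FALSE)
  if (any(!is.finite(ok)) || any(ok <= 0)) {
    stop("costs must be finite and strictly positive", call. = FALSE)
  }
  new_omc_raster(values, cell_size, origin, "omc_cost_raster")
}

#' @rdname omc_raster
#' @export
category_raster <- function(values, categories, cell_size = 1, origin = c(0, 0)) {
  values <- as_value_matrix(values)
  categories <- as.integer(categories)
  ok <- values[!is.na(values)]
  if (length(ok) && !all(ok %in% categories)) {
    stop("all non-missing cells must carry a schema category code",
         call. = FALSE)
  }
  storage.mode(values) <- "integer"
  r <- new_omc_raster(values, cell_size, origin, "omc_category_raster")
  r$categories <- categories
  r
}

#' @rdname omc_raster
#' @export
current_map <- function(values, cell_size = 1, origin = c(0, 0)) {
  values <- as_value_matrix(values)
  ok <- values[!is.na(values)]
  if (any(!is.finite(ok)) || any(ok < -1e-12)) {
    stop("current density must be finite and nonnegative", call. = FALSE)
  }
  new_omc_raster(values, cell_size, origin, "omc_current_map")
}

as_value_matrix <- function(values) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  values
}

#' @export
dim.omc_raster <- function(x) dim(x$values)

#' @export
print.omc_raster <- function(x, ...) {
  kind <- setdiff(class(x), "omc_raster")[1]
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<%s> %d x %d cells, cell size %g, origin (%g, %g)\n",
              kind, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d masked\n", min(v), max(v),
                sum(is.na(x$values))))
  }
  invisible(x)
}

#' Cell-center coordinates and point-to-cell lookup
#'
#' `cell_centers()` returns the map coordinates of every cell center;
#' `cells_at()` maps point coordinates to (row, col) indices under the
#' half-open cell convention. Points outside the grid get `NA` indices.
#'
#' @param raster An `omc_raster`.
#' @param x,y Numeric vectors of point coordinates.
#' @return A tibble: `row`, `col`, `x`, `y` for `cell_centers()`;
#'   `row`, `col` for `cells_at()`.
#' @export
cell_centers <- function(raster) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  cs <- raster$cell_size
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = raster$origin[1] + (rep(seq_len(nc), each = nr) - 0.5) * cs,
    y = raster$origin[2] - (rep(seq_len(nr), times = nc) - 0.5) * cs
  )
}

#' @rdname cell_centers
#' @export
cells_at <- function(raster, x, y) {
  cs <- raster$cell_size
  col <- floor((x - raster$origin[1]) / cs) + 1
  row <- floor((raster$origin[2] - y) / cs) + 1
  bad <- row < 1 | row > nrow(raster$values) | col < 1 | col > ncol(raster$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.omc_raster <- function(x, ...) {
  out <- cell_centers(x)
  out$value <- as.vector(x$values)
  out
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange in the ESRI ASCII grid (`.asc`) format:
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values, northernmost row first.
#'
#' @param path File path.
#' @param raster An `omc_raster` to write.
#' @param kind One of `"cost"`, `"current"`, `"category"`; chooses the class
#'   of the object returned by `read_ascii_grid()`.
#' @param categories Category codes, required when `kind = "category"`.
#' @return `read_ascii_grid()` returns an `omc_raster`; `write_ascii_grid()`
#'   returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, kind = c("cost", "current", "category"),
                            categories = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop("ASCII grid body does not match header dimensions", call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  switch(kind,
    cost = cost_raster(m, hdr$cellsize, origin),
    current = current_map(m, hdr$cellsize, origin),
    category = category_raster(m, categories %||% sort(unique(stats::na.omit(as.vector(m)))),
                               hdr$cellsize, origin))
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(raster, path) {
  m <- raster$values
  nodata <- -9999
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", raster$origin[2] - nrow(m) * raster$cell_size),
    sprintf("cellsize %.10g", raster$cell_size),
    sprintf("NODATA_value %d", nodata)
  )
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, digits = 15),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
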