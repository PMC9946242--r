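#' Cut road polylines into fixed-length sections
#'
#' Each polyline is divided into consecutive sections of `section_length`
#' (900 m by default) measured along the line from its start. A terminal
#' remainder at least half the section length is kept as a (flagged) short
#' section; shorter remainders are dropped.
#'
#' @param roads Features tibble of LineStrings (see [features_tbl()]).
#' @param section_length Section length in map units.
#' @return A tibble: `section_id`, `road_id`, `geometry` (list of coordinate
#'   matrices), `length`, `remainder` (flag).
#' @examples
#' r <- features_tbl(cbind(c(0, 2700), c(0, 0)))
#' nrow(road_sections(r, 900))  # 3 sections
#' @export
road_sections <- function(roads, section_length = 900) {
  if (section_length <= 0) stop("section_length must be positive", call. = FALSE)
  out <- list()
  for (k in seq_len(nrow(roads))) {
    coords <- roads$coords[[k]]
    seg <- diff(coords)
    seg_len <- sqrt(rowSums(seg^2))
    total <- sum(seg_len)
    if (total <= 0) next
    n_full <- floor(total / section_length)
    rem <- total - n_full * section_length
    breaks <- seq(0, n_full * section_length, by = section_length)
    keep_rem <- rem >= section_length / 2
    if (keep_rem) breaks <- c(breaks, total)
    for (s in seq_len(length(breaks) - 1L)) {
      geom <- substring_line(coords, seg_len, breaks[s], breaks[s + 1L])
      out[[length(out) + 1L]] <- tibble::tibble(
        road_id = roads$id[k],
        geometry = list(geom),
        length = breaks[s + 1L] - breaks[s],
        remainder = keep_rem && s == length(breaks) - 1L &&
          breaks[s + 1L] - breaks[s] < section_length
      )
    }
  }
  if (length(out) == 0L) stop("roads produced no sections", call. = FALSE)
  dplyr::bind_cols(tibble::tibble(section_id = seq_along(out)),
                   dplyr::bind_rows(out))
}

# Extract the sub-polyline between arc-length positions a and b.
substring_line <- function(coords, seg_len, a, b) {
  cum <- c(0, cumsum(seg_len))
  point_at <- function(d) {
    i <- findInterval(d, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(seg_len))
    f <- if (seg_len[i] > 0) (d - cum[i]) / seg_len[i] else 0
    coords[i, ] + f * (coords[i + 1L, ] - coords[i, ])
  }
  inner <- which(cum > a & cum < b)
  rbind(point_at(a),
        if (length(inner)) coords[inner, , drop = FALSE],
        point_at(b))
}

#' Mean current density along road sections
#'
#' For each section, the mean current over the raster cells the section
#' passes through plus a buffer of `buffer_cells` cells around them —
#' current "immediately adjacent" to the road.
#'
#' @param sections Tibble from [road_sections()].
#' @param current An `omc_current_map`.
#' @param buffer_cells Chebyshev buffer width in cells (default 1).
#' @return A tibble: `section_id`, `mean_current`, `n_cells`.
#' @export
section_mean_current <- function(sections, current, buffer_cells = 1) {
  nr <- nrow(current$values); nc <- ncol(current$values)
  off <- expand.grid(dr = -buffer_cells:buffer_cells,
                     dc = -buffer_cells:buffer_cells)
  res <- vapply(seq_len(nrow(sections)), function(k) {
    cells <- line_cells(current, sections$geometry[[k]])
    if (nrow(cells) == 0L) return(c(NA_real_, 0))
    rr <- rep(cells[, 1], each = nrow(off)) + off$dr
    cc <- rep(cells[, 2], each = nrow(off)) + off$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    idx <- unique((cc[ok] - 1L) * nr + rr[ok])
    c(mean(current$values[idx], na.rm = TRUE), length(idx))
  }, numeric(2))
  tibble::tibble(section_id = sections$section_id,
                 mean_current = res[1, ], n_cells = as.integer(res[2, ]))
}

#' Assign event points to their nearest road section
#'
#' @param kills Tibble with `x`, `y`.
#' @param sections Tibble from [road_sections()].
#' @return Integer vector of section ids, one per point.
#' @export
assign_to_sections <- function(kills, sections) {
  vapply(seq_len(nrow(kills)), function(i) {
    p <- c(kills$x[i], kills$y[i])
    d <- vapply(sections$geometry, function(g) point_line_distance(p, g),
                numeric(1))
    sections$section_id[which.min(d)]
  }, integer(1))
}

point_line_distance <- function(p, coords) {
  best <- Inf
  for (s in seq_len(nrow(coords) - 1L)) {
    a <- coords[s, ]; b <- coords[s + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
    t <- min(max(t, 0), 1)
    best <- min(best, sum((p - a - t * ab)^2))
  }
  sqrt(best)
}

#' Road-section roadkill/current rank correlation
#'
#' Divides the roads into fixed-length sections, counts the events assigned
#' to each section (nearest-section rule), extracts each section's mean
#' current density (section cells plus a one-cell buffer), and reports the
#' Spearman rank correlation (mid-ranked ties) between counts and current.
#'
#' @param roads Features tibble of LineStrings.
#' @param kills Either a point tibble (`x`, `y`) to be assigned to sections,
#'   or a count tibble (`section_id`, `count`) as from
#'   [simulate_roadkill()].
#' @param current An `omc_current_map`.
#' @param section_length Section length in map units (default 900).
#' @param buffer_cells Buffer width for the current extraction.
#' @return A one-row tibble: `rho`, `p`, `n_sections`.
#' @export
section_correlation <- function(roads, kills, current, section_length = 900,
                                buffer_cells = 1) {
  sections <- road_sections(roads, section_length)
  if (nrow(sections) < 3L) {
    stop("need at least 3 road sections", call. = FALSE)
  }
  counts <- rep(0L, nrow(sections))
  if (all(c("section_id", "count") %in% names(kills))) {
    idx <- match(kills$section_id, sections$section_id)
    counts[idx[!is.na(idx)]] <- kills$count[!is.na(idx)]
  } else {
    hit <- assign_to_sections(kills, sections)
    tab <- table(hit)
    counts[match(as.integer(names(tab)), sections$section_id)] <- as.integer(tab)
  }
  mc <- section_mean_current(sections, current, buffer_cells)
  ct <- suppressWarnings(
    stats::cor.test(counts, mc$mean_current, method = "spearman",
                    exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value,
                 n_sections = nrow(sections))
}
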