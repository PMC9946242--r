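#' Subsample an individual's observed locations
#'
#' Simple random sample without replacement of `ceiling(fraction * n)` fixes
#' from one individual's track — 10% by default, a common testing ratio that
#' also damps serial autocorrelation between retained fixes.
#'
#' @param track Tibble of one individual's records (`timestamp`, `x`, `y`).
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer RNG seed.
#' @return The sampled rows, in time order.
#' @export
subsample_observed <- function(track, fraction = 0.10, seed = 1) {
  if (nrow(track) == 0L) stop("track is empty", call. = FALSE)
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- ceiling(fraction * nrow(track))
  idx <- sort(sample.int(nrow(track), n))
  track[idx, , drop = FALSE]
}

#' Maximum displacement distance
#'
#' Greatest straight-line distance from any observed location back to the
#' individual's time-earliest location, in map units.
#'
#' @param track Tibble of one individual's records.
#' @return A nonnegative distance; 0 with a warning for a single point.
#' @export
max_displacement <- function(track) {
  if (nrow(track) < 2L) {
    warning("track has a single point; displacement is 0")
    return(0)
  }
  first <- track[which.min(track$timestamp), ]
  max(sqrt((track$x - first$x)^2 + (track$y - first$y)^2))
}

#' Kernel utilization distribution and isopleth mask
#'
#' Gaussian kernel density of the point set evaluated at the cell centers of
#' `grid`, with the reference bandwidth
#' `href = 0.5 * (sd(x) + sd(y)) * n^(-1/6)` unless overridden. The isopleth
#' mask is the smallest set of cells, filled in order of descending density
#' (ties included), whose summed mass reaches the isopleth — the 95% mask is
#' the conventional home-range estimate.
#'
#' @param points Tibble with `x`, `y` (>= 5 points).
#' @param grid Template raster defining the evaluation grid.
#' @param isopleth Mass fraction in (0, 1].
#' @param bandwidth Optional kernel standard deviation in map units.
#' @return A logical matrix mask (same shape as the grid) with attributes
#'   `density` (the normalized density matrix) and `bandwidth`.
#' @export
kernel_ud <- function(points, grid, isopleth = 0.95, bandwidth = NULL) {
  if (nrow(points) < 5L) stop("need at least 5 points", call. = FALSE)
  if (!(isopleth > 0 && isopleth <= 1)) {
    stop("isopleth must be in (0, 1]", call. = FALSE)
  }
  if (is.null(bandwidth)) {
    bandwidth <- 0.5 * (stats::sd(points$x) + stats::sd(points$y)) *
      nrow(points)^(-1 / 6)
  }
  coincident <- !is.finite(bandwidth) || bandwidth <= 0
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (coincident) {
    warning("all points coincident; mask is the single containing cell")
    mask <- matrix(FALSE, nr, nc)
    cell <- cells_at(grid, points$x[1], points$y[1])
    mask[cell$row, cell$col] <- TRUE
    attr(mask, "bandwidth") <- 0
    return(mask)
  }
  cs <- grid$cell_size
  xc <- grid$origin[1] + (seq_len(nc) - 0.5) * cs
  yc <- grid$origin[2] - (seq_len(nr) - 0.5) * cs
  # separable product kernel: D[r, c] = sum_i phi(dy_ri) phi(dx_ci)
  A <- stats::dnorm(outer(yc, points$y, "-") / bandwidth)
  B <- stats::dnorm(outer(xc, points$x, "-") / bandwidth)
  D <- A %*% t(B)
  D <- D / sum(D)
  if (isopleth >= 1) {
    mask <- D > 0  # every cell with nonzero density
  } else {
    ord <- order(D, decreasing = TRUE)
    cum <- cumsum(D[ord])
    need <- which(cum >= isopleth)[1]
    if (is.na(need)) need <- length(ord)
    thresh <- D[ord[need]]
    mask <- D >= thresh  # ties at the threshold density are included
  }
  attr(mask, "density") <- D
  attr(mask, "bandwidth") <- bandwidth
  mask
}

#' Sample available locations from a buffered home range
#'
#' Dilates the utilization-distribution mask by the individual's maximum
#' displacement distance (Euclidean, clipped to the grid) and draws points
#' uniformly over the dilated region: a cell is drawn uniformly, then a
#' position uniformly within it.
#'
#' @param mask Logical home-range mask from [kernel_ud()].
#' @param d_max Dilation radius in map units (0 keeps the mask itself).
#' @param n Number of points (>= 1).
#' @param grid Template raster the mask lives on.
#' @param seed Integer RNG seed.
#' @return Tibble with `x`, `y`.
#' @export
sample_available <- function(mask, d_max, n, grid, seed = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  region <- dilate_mask(mask, d_max / grid$cell_size)
  cells <- which(region)
  if (length(cells) == 0L) stop("sampling region is empty", call. = FALSE)
  set.seed(as.integer(seed))
  pick <- cells[sample.int(length(cells), n, replace = TRUE)]
  nr <- nrow(mask)
  row <- (pick - 1L) %% nr + 1L
  col <- (pick - 1L) %/% nr + 1L
  cs <- grid$cell_size
  tibble::tibble(
    x = grid$origin[1] + (col - 1L) * cs + stats::runif(n) * cs,
    y = grid$origin[2] - (row - 1L) * cs - stats::runif(n) * cs
  )
}

# Euclidean dilation of a logical mask by a radius in cells (cell-center
# distance transform).
dilate_mask <- function(mask, radius_cells) {
  if (radius_cells <= 0 || !any(mask)) return(mask)
  d <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask)))
  matrix(as.numeric(d) <= radius_cells, nrow(mask))
}

#' Extract current density at points
#'
#' Focal-pixel value by default; with a positive `buffer_radius`, the mean
#' over the focal pixel and all pixels whose centers lie within the radius
#' of the point (centers at exactly the radius are included). Points
#' off-raster are excluded with their count reported in the `n_excluded`
#' attribute.
#'
#' @param points Tibble with `x`, `y`.
#' @param current An `omc_current_map`.
#' @param buffer_radius Radius in map units (default 0).
#' @return Numeric vector of extracted values (one per retained point).
#' @export
extract_current <- function(points, current, buffer_radius = 0) {
  cells <- cells_at(current, points$x, points$y)
  ok <- !is.na(cells$row)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    warning(sprintf("%d point(s) fall outside the raster and were excluded",
                    n_excluded))
  }
  px <- points$x[ok]; py <- points$y[ok]
  if (buffer_radius <= 0) {
    vals <- current$values[cbind(cells$row[ok], cells$col[ok])]
  } else {
    cen <- cell_centers(current)
    vals <- vapply(seq_along(px), function(i) {
      d2 <- (cen$x - px[i])^2 + (cen$y - py[i])^2
      sel <- d2 <= buffer_radius^2 + 1e-9
      sel[(cells$col[ok][i] - 1L) * nrow(current$values) + cells$row[ok][i]] <- TRUE
      mean(current$values[cbind(cen$row[sel], cen$col[sel])], na.rm = TRUE)
    }, numeric(1))
  }
  if (n_excluded > 0) attr(vals, "n_excluded") <- n_excluded
  vals
}

#' Quartile binning into short- and long-distance movers
#'
#' Individuals whose maximum displacement falls in the lower quartile bin
#' (0–0.25 quantile range) are short-distance movers, the upper quartile bin
#' (0.75–1 range) long-distance movers, the rest middle. Quantiles use the
#' linear-interpolation definition; boundary values are inclusive on the
#' outer bins. Rank-based, hence invariant to any strictly increasing
#' transform of the distances.
#'
#' @param d_max Numeric vector of per-individual distances (>= 4 of them).
#' @return Factor with levels `short`, `middle`, `long`.
#' @export
quartile_bins <- function(d_max) {
  if (length(d_max) < 4L) stop("need at least 4 individuals", call. = FALSE)
  q <- stats::quantile(d_max, c(0.25, 0.75), type = 7)
  if (q[1] == q[2]) {
    warning("all distances effectively equal; classifying all as middle")
    return(factor(rep("middle", length(d_max)),
                  levels = c("short", "middle", "long")))
  }
  cls <- ifelse(d_max <= q[1], "short",
                ifelse(d_max >= q[2], "long", "middle"))
  factor(cls, levels = c("short", "middle", "long"))
}

#' Welch t-test and Cohen's d for two point samples
#'
#' Compares mean current densities of event locations (`group_a`, e.g.
#' roadkill) against random locations along the same roads (`group_b`). The
#' default alternative is one-sided — event mean greater — with the
#' two-sided test behind a flag. Cohen's d uses the pooled standard
#' deviation with n-1 denominators.
#'
#' @param group_a,group_b Numeric vectors (each >= 2 values).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A one-row tibble: `t`, `df`, `p`, `cohens_d`, `n_a`, `n_b`.
#' @examples
#' point_ttest(c(0, 2), c(1, 3))  # d = -1/sqrt(2)
#' @export
point_ttest <- function(group_a, group_b,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  na <- length(group_a); nb <- length(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) {
    warning("zero pooled variance; Cohen's d undefined")
    d <- NA_real_
    tt <- list(statistic = 0, parameter = na + nb - 2,
               p.value = if (alternative == "greater") 0.5 else 1)
  } else {
    d <- (mean(group_a) - mean(group_b)) / sqrt(sp2)
    tt <- stats::t.test(group_a, group_b, alternative = alternative,
                        var.equal = FALSE)
  }
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohens_d = d, n_a = na, n_b = nb)
}

#' Assemble a used-versus-available case dataset
#'
#' The full telemetry validation pipeline, per individual: subsample the
#' observed fixes, estimate the home range ([kernel_ud()]) from the full
#' track, compute the maximum displacement, draw an equal number of
#' available points from the displacement-buffered home range
#' ([sample_available()]), and extract current density at both point sets.
#'
#' @param tracks Telemetry tibble (`individual_id`, `timestamp`, `x`, `y`).
#' @param current An `omc_current_map` (also the UD evaluation grid).
#' @param fraction Observed-subsample fraction.
#' @param isopleth UD isopleth.
#' @param buffer_radius Extraction radius in map units (0 = focal pixel).
#' @param seed Integer seed; per-individual streams are derived from it.
#' @return A case tibble: `individual_id`, `case` (1 observed, 0 available),
#'   `current_value`, `d_max` — equal case counts per individual.
#' @export
build_case_data <- function(tracks, current, fraction = 0.10,
                            isopleth = 0.95, buffer_radius = 0, seed = 1) {
  ids <- unique(tracks$individual_id)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    tr <- dplyr::arrange(tracks[tracks$individual_id == ids[k], ], .data$timestamp)
    obs <- subsample_observed(tr, fraction, seed = seed + 7L * k)
    mask <- kernel_ud(tr, current, isopleth)
    dmax <- max_displacement(tr)
    avail <- sample_available(mask, dmax, nrow(obs), current,
                              seed = seed + 7L * k + 3L)
    v_obs <- extract_current(obs, current, buffer_radius)
    v_avl <- extract_current(avail, current, buffer_radius)
    n <- min(length(v_obs), length(v_avl))  # keep cases balanced
    out[[k]] <- tibble::tibble(
      individual_id = ids[k],
      case = rep(c(1L, 0L), each = n),
      current_value = c(v_obs[seq_len(n)], v_avl[seq_len(n)]),
      d_max = dmax
    )
  }
  dplyr::bind_rows(out)
}
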