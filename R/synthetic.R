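#' Generate a patchy category landscape
#'
#' Spatially autocorrelated stand-in for a real multi-layer land-cover
#' composite: white noise is smoothed with a separable Gaussian kernel of
#' standard deviation `patch_scale` cells and then quantized at equal
#' quantiles into the category codes, giving patches of characteristic size
#' about `patch_scale` cells and near-equal category frequencies.
#'
#' @param nrows,ncols Grid dimensions (>= 1).
#' @param categories Integer codes (>= 2 of them), e.g. `schema$codes`.
#' @param patch_scale Patch size parameter in cells (> 0). As it approaches
#'   zero the landscape degenerates to iid noise.
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @param cell_size,origin Georeferencing of the output raster.
#' @return An `omc_category_raster`.
#' @examples
#' land <- generate_patchy_landscape(40, 40, 1:4, patch_scale = 6, seed = 1)
#' table(land$values)
#' @export
generate_patchy_landscape <- function(nrows, ncols, categories, patch_scale,
                                      seed, cell_size = 1, origin = c(0, 0)) {
  if (nrows < 1 || ncols < 1) stop("dimensions must be positive", call. = FALSE)
  categories <- as.integer(categories)
  if (length(categories) < 2L) {
    stop("need at least 2 categories for a patchy landscape", call. = FALSE)
  }
  if (!is.finite(patch_scale) || patch_scale <= 0) {
    stop("patch_scale must be > 0", call. = FALSE)
  }
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(nrows * ncols), nrows, ncols)
  z <- gaussian_smooth(z, patch_scale)
  k <- length(categories)
  cuts <- stats::quantile(z, probs = seq_len(k - 1) / k, type = 7)
  codes <- categories[findInterval(z, cuts) + 1L]
  category_raster(matrix(codes, nrows, ncols), categories, cell_size, origin)
}

# Separable Gaussian smoothing with reflection at the borders, done as two
# banded matrix products so the result is exactly reproducible.
gaussian_smooth <- function(m, sigma) {
  smoother <- function(n) {
    if (sigma < 1e-3) return(diag(n))
    half <- max(1L, ceiling(3 * sigma))
    idx <- seq_len(n)
    S <- outer(idx, idx, function(a, b) {
      d <- abs(a - b)
      ifelse(d <= half, stats::dnorm(d, sd = sigma), 0)
    })
    # reflect mass that falls off the edge back onto the border rows
    S / rowSums(S)
  }
  as.matrix(smoother(nrow(m)) %*% m %*% t(smoother(ncol(m))))
}

#' Generate a 50/50 split cost landscape
#'
#' The simplistic landscape of the tile-size sensitivity analysis: an n x n
#' raster with exactly half the cells at a low cost and half at a high cost,
#' split down the middle. `orientation = "vertical"` puts the split line
#' vertically (west half low, east half high); `"horizontal"` puts it
#' horizontally (north half low).
#'
#' @param n Even side length.
#' @param low_cost,high_cost Costs with `0 < low_cost < high_cost`.
#' @param orientation `"vertical"` or `"horizontal"`.
#' @param cell_size,origin Georeferencing.
#' @return An `omc_cost_raster`.
#' @export
generate_split_landscape <- function(n, low_cost = 1, high_cost = 1000,
                                     orientation = c("vertical", "horizontal"),
                                     cell_size = 1, origin = c(0, 0)) {
  orientation <- match.arg(orientation)
  if (n %% 2 != 0) stop("n must be even for an exact 50/50 split", call. = FALSE)
  if (!(low_cost > 0 && low_cost < high_cost)) {
    stop("need 0 < low_cost < high_cost", call. = FALSE)
  }
  m <- matrix(low_cost, n, n)
  if (orientation == "vertical") {
    m[, (n / 2 + 1):n] <- high_cost
  } else {
    m[(n / 2 + 1):n, ] <- high_cost
  }
  cost_raster(m, cell_size, origin)
}

#' Configuration for synthetic telemetry tracks
#'
#' @param n_individuals Number of simulated animals (>= 1).
#' @param steps_per_individual Baseline number of relocation steps (>= 1).
#' @param preference_strength Weight (beta) on standardized current density
#'   in the step-choice kernel; 0 gives an unbiased walk.
#' @param displacement_coupling Spread of per-individual walk lengths: step
#'   counts are scaled by multipliers ranging over
#'   `exp(+/- displacement_coupling)`, so maximum displacement varies across
#'   individuals. 0 makes all walks the same length.
#' @param preference_exponent Exponent linking preference to walk length:
#'   individual `i`'s beta is `preference_strength * m_i^preference_exponent`
#'   where `m_i` is its length multiplier. Positive values make
#'   longer-ranging individuals select more strongly, the generative pattern
#'   behind the case-by-displacement interaction test.
#' @param drift Directional persistence scale: individual `i` gets an extra
#'   log-weight `drift * m_i` on the component of each step along its own
#'   fixed heading. Scaling the drift with the multiplier makes large-`m_i`
#'   individuals genuinely long-distance movers: their travel urge outweighs
#'   habitat preference, whereas a biased walk alone concentrates in good
#'   habitat instead of ranging. 0 disables drift.
#' @param start_time POSIXct origin for timestamps.
#' @param step_minutes Minutes between fixes.
#' @param seed Integer RNG seed.
#' @return An `omc_track_config`.
#' @export
track_config <- function(n_individuals, steps_per_individual,
                         preference_strength = 0, displacement_coupling = 0,
                         preference_exponent = 0, drift = 0,
                         start_time = as.POSIXct("2020-01-01 00:00:00",
                                                tz = "UTC"),
                         step_minutes = 60, seed = 1) {
  if (n_individuals < 1 || steps_per_individual < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 steps_per_individual = as.integer(steps_per_individual),
                 preference_strength = preference_strength,
                 displacement_coupling = displacement_coupling,
                 preference_exponent = preference_exponent,
                 drift = drift,
                 start_time = start_time, step_minutes = step_minutes,
                 seed = as.integer(seed)),
            class = "omc_track_config")
}

#' Simulate preference-biased lattice tracks
#'
#' Each individual performs a walk on the raster lattice: from its current
#' cell, the next cell among the 8-neighbours is chosen with probability
#' proportional to `exp(beta * z)`, where `z` is the current density
#' standardized to zero mean and unit variance over the map; proposals that
#' would leave the grid keep the animal in place instead. Track coordinates
#' are emitted at pixel centers in map units with strictly increasing
#' timestamps. `beta = 0` yields an unbiased walk whose stationary
#' distribution is exactly uniform over the grid (the step kernel is doubly
#' stochastic), so per-cell visit frequencies are uniform up to sampling
#' noise.
#'
#' @param current An `omc_current_map` (finite, nonnegative).
#' @param config An [track_config()].
#' @return A telemetry tibble: `individual_id`, `timestamp`, `x`, `y`.
#' @export
simulate_tracks <- function(current, config) {
  v <- current$values
  if (length(v) == 0L || all(is.na(v))) stop("empty current map", call. = FALSE)
  if (any(!is.finite(v[!is.na(v)])) || any(v[!is.na(v)] < 0)) {
    stop("current map must be finite and nonnegative", call. = FALSE)
  }
  nr <- nrow(v); nc <- ncol(v)
  z <- (v - mean(v, na.rm = TRUE)) / max(stats::sd(v, na.rm = TRUE), 1e-12)
  z[is.na(z)] <- -Inf  # masked cells are never stepped into
  set.seed(config$seed)
  n_ind <- config$n_individuals
  mult <- if (n_ind == 1L) 1 else {
    exp(seq(-config$displacement_coupling, config$displacement_coupling,
            length.out = n_ind))
  }
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  out <- vector("list", n_ind)
  headings <- (seq_len(n_ind) - 1L) %% 8L + 1L
  for (i in seq_len(n_ind)) {
    beta <- config$preference_strength * mult[i]^config$preference_exponent
    drift_w <- config$drift * mult[i]
    head_r <- off_r[headings[i]] / sqrt(pmax(off_r[headings[i]]^2 + off_c[headings[i]]^2, 1))
    head_c <- off_c[headings[i]] / sqrt(pmax(off_r[headings[i]]^2 + off_c[headings[i]]^2, 1))
    n_steps <- max(2L, as.integer(round(config$steps_per_individual * mult[i])))
    rr <- integer(n_steps); cc <- integer(n_steps)
    repeat {
      r0 <- sample.int(nr, 1L); c0 <- sample.int(nc, 1L)
      if (is.finite(z[r0, c0])) break
    }
    rr[1] <- r0; cc[1] <- c0
    for (s in 2:n_steps) {
      nbr_r <- rr[s - 1L] + off_r; nbr_c <- cc[s - 1L] + off_c
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      # blocked proposals keep the animal in place, so the unbiased walk is
      # doubly stochastic and its stationary law is uniform over the grid
      nbr_r[!ok] <- rr[s - 1L]; nbr_c[!ok] <- cc[s - 1L]
      along <- (off_r * head_r + off_c * head_c) /
        sqrt(off_r^2 + off_c^2)
      along[!ok] <- 0
      w <- exp(beta * z[cbind(nbr_r, nbr_c)] + drift_w * along)
      w[!is.finite(w)] <- 0
      if (all(w == 0)) w <- rep(1, length(w))
      k <- sample.int(8L, 1L, prob = w)
      rr[s] <- nbr_r[k]; cc[s] <- nbr_c[k]
    }
    out[[i]] <- tibble::tibble(
      individual_id = sprintf("ind_%02d", i),
      timestamp = config$start_time +
        (seq_len(n_steps) - 1L) * 60 * config$step_minutes,
      x = current$origin[1] + (cc - 0.5) * current$cell_size,
      y = current$origin[2] - (rr - 0.5) * current$cell_size
    )
  }
  dplyr::bind_rows(out)
}

#' Read and write telemetry CSV
#'
#' Plain CSV with header `individual_id,timestamp,x,y` and ISO-8601 UTC
#' timestamps.
#'
#' @param tracks A telemetry tibble.
#' @param path File path.
#' @export
write_telemetry_csv <- function(tracks, path) {
  out <- dplyr::mutate(tracks,
    timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_telemetry_csv
#' @export
read_telemetry_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(
    individual_id = as.character(raw$individual_id),
    timestamp = as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC"),
    x = as.numeric(raw$x), y = as.numeric(raw$y)
  )
}

#' Simulate roadkill counts along road sections
#'
#' Ground truth for the road-section correlation test: the count for section
#' `s` is Poisson with log-intensity
#' `intercept + slope * mean_current(s)`, where the section's mean current
#' is taken over the raster cells the section touches plus a one-cell
#' buffer (the same extraction used by [section_correlation()]).
#'
#' @param sections A road-section tibble from [road_sections()].
#' @param current An `omc_current_map`.
#' @param intercept,slope Log-linear intensity coefficients.
#' @param seed Integer RNG seed.
#' @return A tibble: `section_id`, `count`.
#' @export
simulate_roadkill <- function(sections, current, intercept, slope, seed) {
  mc <- section_mean_current(sections, current)
  if (anyNA(mc$mean_current)) {
    stop("every section must overlap the current map", call. = FALSE)
  }
  set.seed(as.integer(seed))
  lambda <- exp(intercept + slope * mc$mean_current)
  tibble::tibble(section_id = mc$section_id,
                 count = stats::rpois(nrow(mc), lambda))
}
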