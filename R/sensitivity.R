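#' A table of cost scenarios
#'
#' Bundles two or more [cost_schema()] scenarios sharing one category set,
#' for the cost-scenario sensitivity analysis.
#'
#' @param ... `omc_cost_schema` objects (or a single list of them).
#' @return An `omc_scenario_table` (a named list of schemas).
#' @examples
#' scenario_table(
#'   cost_schema(c(low = 1, ml = 2, mh = 3, high = 4), name = "narrow"),
#'   cost_schema(c(low = 1, ml = 10, mh = 100, high = 1000), name = "wide")
#' )
#' @export
scenario_table <- function(...) {
  scen <- list(...)
  if (length(scen) == 1L && !inherits(scen[[1]], "omc_cost_schema")) {
    scen <- scen[[1]]
  }
  if (length(scen) < 2L) stop("need at least 2 scenarios", call. = FALSE)
  k <- length(scen[[1]]$costs)
  for (s in scen) {
    if (!inherits(s, "omc_cost_schema")) {
      stop("scenarios must be cost schemas", call. = FALSE)
    }
    if (length(s$costs) != k) {
      stop("scenarios must share one category set", call. = FALSE)
    }
  }
  names(scen) <- vapply(scen, `[[`, character(1), "name")
  structure(scen, class = "omc_scenario_table")
}

#' Cost-scenario sensitivity of current density
#'
#' For each scenario, builds the cost raster from the category landscape,
#' runs the full omnidirectional analysis, samples the *same* seeded random
#' cells from every scenario's map, and computes all pairwise Spearman rank
#' correlations (ties mid-ranked). A pair whose sampled values have zero
#' variance gets `NA` with a warning. High correlations across scenarios
#' that share the category rank order are what justifies treating the map
#' as robust to the absolute cost values.
#'
#' @param categories An `omc_category_raster` landscape.
#' @param scenarios An [scenario_table()].
#' @param n_cells Number of sampled cells (default 1000).
#' @param seed Integer seed for the cell sample (recorded in the result).
#' @param ... Passed to [omnidirectional_current()].
#' @return An `omc_sensitivity`: `rho` (symmetric matrix, unit diagonal),
#'   `mean_rho` (tibble of per-scenario mean correlation with the others),
#'   `max_current` (per-scenario map maximum), `cells` (sampled linear cell
#'   indices), `seed`.
#' @export
scenario_correlations <- function(categories, scenarios, n_cells = 1000,
                                  seed = 1, ...) {
  n_total <- length(categories$values)
  if (n_cells > n_total) {
    stop("n_cells exceeds the number of cells", call. = FALSE)
  }
  set.seed(as.integer(seed))
  cells <- sample.int(n_total, n_cells)
  nm <- names(scenarios)
  samples <- list(); max_cur <- numeric(length(scenarios))
  for (k in seq_along(scenarios)) {
    cost <- combine_layers(list(categories), scenarios[[k]])
    omni <- omnidirectional_current(cost, ...)
    samples[[k]] <- omni$values[cells]
    max_cur[k] <- max(omni$values, na.rm = TRUE)
  }
  p <- length(scenarios)
  rho <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  diag(rho) <- 1
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      if (stats::sd(samples[[a]]) == 0 || stats::sd(samples[[b]]) == 0) {
        warning(sprintf("constant current values; rho undefined for %s-%s",
                        nm[a], nm[b]))
      } else {
        rho[a, b] <- rho[b, a] <-
          stats::cor(samples[[a]], samples[[b]], method = "spearman")
      }
    }
  }
  off <- rho; diag(off) <- NA
  structure(
    list(rho = rho,
         mean_rho = tibble::tibble(scenario = nm,
                                   mean_rho = rowMeans(off, na.rm = TRUE)),
         max_current = stats::setNames(max_cur, nm),
         cells = cells, seed = as.integer(seed)),
    class = "omc_sensitivity"
  )
}

#' @export
print.omc_sensitivity <- function(x, ...) {
  cat("<cost-scenario sensitivity>\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' @rdname tidy.omc_model_fit
#' @export
tidy.omc_sensitivity <- function(x, ...) {
  nm <- rownames(x$rho)
  out <- tidyr::expand_grid(scenario_a = nm, scenario_b = nm)
  out$rho <- as.vector(t(x$rho))
  out[out$scenario_a < out$scenario_b, ]
}

#' Select the consensus cost scenario
#'
#' The scenario most strongly correlated with all the others: the argmax of
#' mean off-diagonal Spearman rho (missing pairs averaged over defined
#' entries). Ties go to the earliest scenario, with a message.
#'
#' @param result An `omc_sensitivity`.
#' @return The selected scenario name.
#' @export
select_scenario <- function(result) {
  m <- result$mean_rho$mean_rho
  if (all(!is.finite(m))) stop("all scenario pairs undefined", call. = FALSE)
  best <- which(m == max(m, na.rm = TRUE))
  if (length(best) > 1L) {
    message("tie on mean correlation; keeping the first scenario")
  }
  result$mean_rho$scenario[best[1]]
}

#' Tile-size sensitivity on split landscapes
#'
#' For each candidate tile size, generates the 50/50 split landscape, runs
#' the omnidirectional analysis and records the minimum, maximum, mean and
#' standard deviation of current density over all cells. Successive changes
#' in these statistics shrinking with size is what identifies the tile size
#' above which estimates stabilize.
#'
#' @param sizes Even side lengths, each >= 4.
#' @param low_cost,high_cost Split-landscape costs.
#' @param orientation Split orientation.
#' @param ... Passed to [omnidirectional_current()].
#' @return Tibble: `size`, `min`, `max`, `mean`, `sd`.
#' @export
tile_size_sensitivity <- function(sizes, low_cost = 1, high_cost = 1000,
                                  orientation = "vertical", ...) {
  if (any(sizes < 4) || any(sizes %% 2 != 0)) {
    stop("sizes must be even and >= 4", call. = FALSE)
  }
  rows <- lapply(sizes, function(n) {
    omni <- omnidirectional_current(
      generate_split_landscape(n, low_cost, high_cost, orientation), ...)
    v <- omni$values
    tibble::tibble(size = n, min = min(v), max = max(v),
                   mean = mean(v), sd = stats::sd(v))
  })
  dplyr::bind_rows(rows)
}
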