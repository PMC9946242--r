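#' Monte-Carlo random-walk usage of a cost landscape
#'
#' Independent stochastic counterpart of the deterministic circuit solve:
#' walkers start uniformly on the one-pixel source strip along one raster
#' edge, step to a neighbouring cell with probability proportional to the
#' edge conductance (identical conductance convention and 8-connected
#' topology as [build_network()]), and are absorbed on the opposite strip.
#' The expected *net* number of crossings of an edge by such a walker equals
#' the current on that edge in the equivalent circuit — the precise sense in
#' which current density is proportional to the probability of use during a
#' random walk. The returned map is therefore the per-cell usage estimate
#' assembled exactly like [node_currents()] (half the summed absolute net
#' edge crossings plus half the start/absorption share), and converges to
#' the hard-ground directional current-density map as walkers accumulate;
#' it serves as an implementation-independent oracle for the solver. Gross
#' per-cell visit counts are kept in the `"visits"` attribute.
#'
#' Walkers exceeding the step cap (default `100 * (nrows + ncols)`) are
#' discarded and counted; more than 1% discarded raises a warning.
#'
#' @param cost An `omc_cost_raster` (no masked cells).
#' @param source_side `"north"`, `"south"`, `"east"` or `"west"`; the
#'   opposite side absorbs.
#' @param n_walkers Number of walkers (>= 1).
#' @param seed Integer RNG seed.
#' @param connectivity 8 (default) or 4.
#' @param step_cap Maximum steps per walker.
#' @return An `omc_current_map` of per-cell usage (amperes per unit
#'   injection) with attributes `visits` (gross visit-count matrix),
#'   `absorbed` and `discarded` (`absorbed + discarded == n_walkers`).
#' @export
random_walk_visits <- function(cost, source_side = c("north", "south", "east", "west"),
                               n_walkers, seed, connectivity = 8,
                               step_cap = NULL) {
  source_side <- match.arg(source_side)
  if (n_walkers < 1) stop("n_walkers must be >= 1", call. = FALSE)
  if (anyNA(cost$values)) {
    stop("the walker oracle requires an unmasked cost raster", call. = FALSE)
  }
  nr <- nrow(cost$values); nc <- ncol(cost$values)
  if (is.null(step_cap)) step_cap <- 100L * (nr + nc)
  net <- build_network(cost, connectivity)
  k <- if (connectivity == 8) 8L else 4L
  nbr <- matrix(-1L, net$n_nodes, k)
  gmat <- matrix(0, net$n_nodes, k)
  e <- net$edges
  slot <- integer(net$n_nodes)
  put <- function(a, b, g) {
    for (idx in seq_along(a)) {
      s <- slot[a[idx]] + 1L
      slot[a[idx]] <<- s
      nbr[a[idx], s] <<- b[idx] - 1L
      gmat[a[idx], s] <<- g[idx]
    }
  }
  put(e$i, e$j, e$g)
  put(e$j, e$i, e$g)
  cum <- gmat / rowSums(gmat)
  cum <- t(apply(cum, 1L, cumsum))
  cum[, k] <- 1.0 + 1e-12
  opposite <- c(north = "south", south = "north", east = "west", west = "east")
  start <- strip_nodes(net, source_side)
  absorb <- rep(FALSE, net$n_nodes)
  absorb[strip_nodes(net, opposite[[source_side]])] <- TRUE
  set.seed(as.integer(seed))
  res <- .walk_visits_cpp(nbr, cum, start - 1L, absorb,
                          as.integer(n_walkers), as.integer(step_cap))
  if (res$discarded > 0.01 * n_walkers) {
    warning(sprintf("%d of %d walkers hit the step cap and were discarded",
                    res$discarded, n_walkers))
  }
  # net crossings per neighbour slot -> per-cell usage, assembled like
  # node_currents(): usage = (sum |edge current| + injection + absorption)/2
  filled <- which(nbr >= 0L, arr.ind = TRUE)
  i_cell <- filled[, 1]
  j_cell <- nbr[filled] + 1L
  key <- paste(i_cell, j_cell)
  rev_idx <- match(paste(j_cell, i_cell), key)
  net_flow <- (res$flow[filled] - res$flow[filled[rev_idx, , drop = FALSE]]) /
    n_walkers
  usage_nodes <- rowsum(abs(net_flow), group = i_cell)
  usage <- numeric(net$n_nodes)
  usage[as.integer(rownames(usage_nodes))] <- usage_nodes[, 1]
  usage <- (usage + res$starts / n_walkers + res$ends / n_walkers) / 2
  # walkers carry 1 A in total; the directional protocol injects 1 A per
  # source cell, so scale by the strip length to match its units
  usage <- usage * length(start)
  out <- matrix(NA_real_, nr, nc)
  out[net$cell_of] <- usage
  vis_m <- matrix(NA_real_, nr, nc)
  vis_m[net$cell_of] <- res$visits
  map <- current_map(out, cost$cell_size, cost$origin)
  attr(map, "visits") <- vis_m
  attr(map, "absorbed") <- res$absorbed
  attr(map, "discarded") <- res$discarded
  map
}
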