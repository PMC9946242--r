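#' Directional wall-to-wall current density
#'
#' One run of the wall-to-wall protocol: a one-pixel-wide source strip along
#' one edge of the raster, the opposite edge as the ground strip, a fixed
#' current injected at every source cell, and the resulting per-cell current
#' density. Direction names give source then destination: `"N-S"` injects
#' along the northern edge and drains along the southern.
#'
#' Injection is per source cell (1 A each by default), the advanced-mode
#' convention of the circuit tools this protocol mirrors. Keeping the
#' per-cell injection fixed makes current magnitudes comparable across
#' rasters and tiles of different sizes, which is what allows differently
#' sized tiles to be stitched and averaged into one seamless map.
#'
#' With the default `ground = "balanced"` sink, a run and its reverse are
#' identical by linearity; with `ground = "hard"` (classic 0 V ground strip)
#' they can differ slightly, which is the historical reason the protocol
#' averages all four cardinal runs.
#'
#' @param cost An `omc_cost_raster` (at least 3 cells along the flow
#'   direction).
#' @param direction One of `"N-S"`, `"S-N"`, `"E-W"`, `"W-E"`.
#' @param connectivity Passed to [build_network()].
#' @param injection Current injected at each source-strip cell, amperes.
#' @param ground Ground-strip treatment, see [solve_flow()].
#' @param net Optional pre-built network for `cost` (avoids rebuilding).
#' @return An `omc_current_map`.
#' @export
directional_run <- function(cost, direction = c("N-S", "S-N", "E-W", "W-E"),
                            connectivity = 8, injection = 1,
                            ground = c("balanced", "hard"), net = NULL) {
  direction <- match.arg(direction)
  ground <- match.arg(ground)
  span <- if (direction %in% c("N-S", "S-N")) nrow(cost$values) else ncol(cost$values)
  if (span < 3L) {
    stop("raster must be at least 3 cells long in the flow direction",
         call. = FALSE)
  }
  if (is.null(net)) net <- build_network(cost, connectivity)
  ends <- switch(direction,
    "N-S" = c("north", "south"), "S-N" = c("south", "north"),
    "E-W" = c("east", "west"),   "W-E" = c("west", "east"))
  src <- strip_nodes(net, ends[1])
  gnd <- strip_nodes(net, ends[2])
  sol <- solve_flow(net, src, gnd, injections = rep(injection, length(src)),
                    ground = ground)
  node_currents(net, sol)
}

#' Omnidirectional current-density map
#'
#' Runs the wall-to-wall protocol in all four cardinal directions and
#' averages the four maps cell-wise into a single omnidirectional
#' current-density surface, removing the dependence on any particular choice
#' of source and destination.
#'
#' @inheritParams directional_run
#' @param keep_directional If `TRUE`, the four directional maps are attached
#'   as the `"directional"` attribute.
#' @return An `omc_current_map` (the four-run mean).
#' @examples
#' omni <- omnidirectional_current(cost_raster(matrix(1, 5, 5)))
#' @export
omnidirectional_current <- function(cost, connectivity = 8,
                                    injection = 1,
                                    ground = c("balanced", "hard"),
                                    keep_directional = FALSE) {
  ground <- match.arg(ground)
  if (nrow(cost$values) < 3L || ncol(cost$values) < 3L) {
    stop("raster must be at least 3 x 3", call. = FALSE)
  }
  net <- build_network(cost, connectivity)
  dirs <- c("N-S", "S-N", "E-W", "W-E")
  maps <- lapply(dirs, function(d) {
    directional_run(cost, d, connectivity, injection, ground, net = net)
  })
  names(maps) <- dirs
  acc <- Reduce(`+`, lapply(maps, function(m) m$values))
  out <- current_map(acc / 4, cost$cell_size, cost$origin)
  if (keep_directional) attr(out, "directional") <- maps
  out
}
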