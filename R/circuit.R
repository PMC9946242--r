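#' Build the resistor network of a cost raster
#'
#' Every non-masked cell becomes a node; neighbouring cells are joined by a
#' resistor whose resistance is the arithmetic mean of the two cell costs,
#' scaled by the inter-center distance factor (1 for orthogonal neighbours,
#' sqrt(2) for diagonals). Conductance is the reciprocal. The default
#' 8-neighbour connectivity matches the convention of the circuit tools this
#' package mirrors; 4-neighbour is available.
#'
#' @param cost An `omc_cost_raster`; `NA` cells are excluded from the graph.
#' @param connectivity 8 (default) or 4.
#' @return An `omc_network`: node bookkeeping, an edge table
#'   (`i`, `j`, `g` = conductance), and the sparse graph Laplacian.
#' @examples
#' net <- build_network(cost_raster(matrix(c(1, 3), 1)))
#' net$edges  # single edge, r = 2, g = 0.5
#' @export
build_network <- function(cost, connectivity = 8) {
  if (!inherits(cost, "omc_cost_raster")) {
    stop("`cost` must be a cost raster", call. = FALSE)
  }
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  m <- cost$values
  nr <- nrow(m); nc <- ncol(m)
  node_of <- matrix(NA_integer_, nr, nc)
  keep <- which(!is.na(m))
  node_of[keep] <- seq_along(keep)
  n <- length(keep)

  pair <- function(a, b, df) {
    a <- as.vector(a); b <- as.vector(b)
    ia <- node_of[a]; ib <- node_of[b]
    ok <- !is.na(ia) & !is.na(ib)
    g <- 1 / (df * (m[a][ok] + m[b][ok]) / 2)
    list(i = ia[ok], j = ib[ok], g = g)
  }
  idx <- matrix(seq_len(nr * nc), nr, nc)
  pieces <- list(
    pair(idx[, -nc, drop = FALSE], idx[, -1, drop = FALSE], 1),
    pair(idx[-nr, , drop = FALSE], idx[-1, , drop = FALSE], 1)
  )
  if (connectivity == 8 && nr > 1 && nc > 1) {
    pieces <- c(pieces, list(
      pair(idx[-nr, -nc, drop = FALSE], idx[-1, -1, drop = FALSE], sqrt(2)),
      pair(idx[-nr, -1, drop = FALSE], idx[-1, -nc, drop = FALSE], sqrt(2))
    ))
  }
  edges <- tibble::tibble(
    i = unlist(lapply(pieces, `[[`, "i")),
    j = unlist(lapply(pieces, `[[`, "j")),
    g = unlist(lapply(pieces, `[[`, "g"))
  )
  L <- Matrix::sparseMatrix(
    i = c(edges$i, edges$j, seq_len(n)),
    j = c(edges$j, edges$i, seq_len(n)),
    x = c(-edges$g, -edges$g,
          as.vector(Matrix::sparseMatrix(i = c(edges$i, edges$j),
                                         j = rep(1L, 2 * nrow(edges)),
                                         x = rep(edges$g, 2),
                                         dims = c(n, 1)))),
    dims = c(n, n)
  )
  structure(
    list(n_nodes = n, node_of = node_of, cell_of = keep,
         edges = edges, laplacian = Matrix::forceSymmetric(L),
         connectivity = connectivity,
         dims = c(nr, nc), cell_size = cost$cell_size, origin = cost$origin),
    class = "omc_network"
  )
}

#' @export
print.omc_network <- function(x, ...) {
  cat(sprintf("<resistor network> %d nodes, %d edges, %d-connected (%d x %d grid)\n",
              x$n_nodes, nrow(x$edges), x$connectivity, x$dims[1], x$dims[2]))
  invisible(x)
}

node_components <- function(net) {
  g <- igraph::make_empty_graph(net$n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, rbind(net$edges$i, net$edges$j))
  igraph::components(g)$membership
}

#' Solve Kirchhoff current flow on a resistor network
#'
#' Injects current at source nodes and lets it exit through ground nodes,
#' solving the graph-Laplacian system with sparse Cholesky factorization.
#' Two ground treatments are available:
#'
#' * `"hard"` — ground nodes are fixed at 0 V (their rows/columns are
#'   eliminated); the absorbed current distributes itself across the ground
#'   set as the solve dictates. This is the classic advanced-mode setup.
#' * `"balanced"` — ground nodes are uniform sinks: each extracts an equal
#'   share of the total injection, and the (singular) full system is solved
#'   with one node pinned per component. Exchanging source and ground sets
#'   then negates all currents exactly, which is what makes opposite
#'   directional runs of the wall-to-wall protocol coincide.
#'
#' @param net An `omc_network`.
#' @param sources Integer node ids receiving current.
#' @param grounds Integer node ids where current exits; disjoint from
#'   `sources`.
#' @param injections Per-source injected current (amperes); defaults to
#'   `total_injection` split evenly.
#' @param total_injection Total current when `injections` is not given.
#' @param ground `"hard"` or `"balanced"`.
#' @return An `omc_flow`: node potentials `v`, the full injection vector
#'   (ground absorptions negative), the max-norm residual, and the inputs.
#' @export
solve_flow <- function(net, sources, grounds, injections = NULL,
                       total_injection = 1, ground = c("hard", "balanced")) {
  ground <- match.arg(ground)
  sources <- as.integer(sources); grounds <- as.integer(grounds)
  if (length(sources) == 0L || length(grounds) == 0L) {
    stop("sources and grounds must be nonempty", call. = FALSE)
  }
  if (length(intersect(sources, grounds))) {
    stop("sources and grounds must be disjoint", call. = FALSE)
  }
  if (is.null(injections)) injections <- rep(total_injection / length(sources),
                                             length(sources))
  if (length(injections) != length(sources) || sum(injections) <= 0) {
    stop("need one positive injection total across sources", call. = FALSE)
  }
  n <- net$n_nodes
  L <- net$laplacian
  comp <- node_components(net)
  live <- comp[grounds]
  bad <- !(comp[sources] %in% live)
  if (any(bad)) {
    stop(sprintf("source node(s) %s lie in component(s) %s with no ground",
                 paste(sources[bad], collapse = ","),
                 paste(unique(comp[sources[bad]]), collapse = ",")),
         call. = FALSE)
  }
  i_full <- numeric(n)
  i_full[sources] <- i_full[sources] + injections
  v <- numeric(n)

  if (ground == "hard") {
    unknown <- setdiff(which(comp %in% live), grounds)
    if (length(unknown)) {
      v[unknown] <- as.numeric(chol_solve(L[unknown, unknown, drop = FALSE],
                                          i_full[unknown]))
    }
    absorbed <- -as.numeric(L[grounds, , drop = FALSE] %*% v)
    i_full[grounds] <- -absorbed  # net extraction, reported negative
    resid_nodes <- unknown
  } else {
    i_full[grounds] <- i_full[grounds] - sum(injections) / length(grounds)
    touched <- unique(comp[c(sources, grounds)])
    for (cc in touched) {
      if (abs(sum(i_full[comp == cc])) > 1e-12 * sum(injections)) {
        stop(sprintf("component %d has unbalanced injection: sources and grounds are not connected", cc),
             call. = FALSE)
      }
    }
    members <- which(comp %in% touched)
    pin <- members[!duplicated(comp[members])]
    unknown <- setdiff(members, pin)
    if (length(unknown)) {
      v[unknown] <- as.numeric(chol_solve(L[unknown, unknown, drop = FALSE],
                                          i_full[unknown]))
    }
    resid_nodes <- unknown
  }
  # residual checked before any constant shift of the potentials: shifting a
  # component by a constant leaves L v unchanged mathematically but injects
  # O(|v| * eps) cancellation noise into a recomputed product
  resid <- if (length(resid_nodes)) {
    max(abs((L %*% v)[resid_nodes] - i_full[resid_nodes]))
  } else 0
  if (ground == "balanced") {
    # reference each component's potentials to its mean ground potential
    for (cc in unique(comp[grounds])) {
      gset <- grounds[comp[grounds] == cc]
      sel <- comp == cc
      v[sel] <- v[sel] - mean(v[gset])
    }
  }
  if (resid > 1e-10 * max(abs(i_full))) {
    stop(sprintf("solver residual %.3e exceeds tolerance", resid), call. = FALSE)
  }
  structure(list(v = v, injections = i_full, residual = resid,
                 sources = sources, grounds = grounds, ground = ground),
            class = "omc_flow")
}

# Sparse SPD solve with a couple of iterative-refinement sweeps so the
# residual stays near machine precision even when per-node injections are
# tiny (large strips).
chol_solve <- function(A, b) {
  A <- Matrix::forceSymmetric(A)
  ch <- tryCatch(Matrix::Cholesky(A, LDL = FALSE, perm = TRUE),
                 error = function(e) NULL)
  solve1 <- function(rhs) {
    if (is.null(ch)) Matrix::solve(A, rhs) else Matrix::solve(ch, rhs)
  }
  x <- solve1(b)
  for (k in 1:2) {
    r <- b - as.numeric(A %*% x)
    if (max(abs(r)) <= 1e-14 * max(abs(b))) break
    x <- x + solve1(r)
  }
  x
}

#' Per-cell current density of a flow solution
#'
#' Node current is half the sum of the absolute currents on incident edges,
#' plus half the node's own injection or absorption — without the halving
#' each ampere would be counted once entering and once leaving. The result
#' is mapped back onto the raster grid (masked cells stay `NA`).
#'
#' @param net An `omc_network`.
#' @param sol An `omc_flow` solved on `net`.
#' @return An `omc_current_map`.
#' @export
node_currents <- function(net, sol) {
  e <- net$edges
  I_abs <- abs(e$g * (sol$v[e$i] - sol$v[e$j]))
  s <- numeric(net$n_nodes)
  acc <- rowsum(c(I_abs, I_abs), group = c(e$i, e$j))
  s[as.integer(rownames(acc))] <- acc[, 1]
  s <- (s + abs(sol$injections)) / 2
  out <- matrix(NA_real_, net$dims[1], net$dims[2])
  out[net$cell_of] <- s
  current_map(out, net$cell_size, net$origin)
}

#' Effective resistance between merged node sets
#'
#' Treats all sources as one terminal and all grounds as the other (Dirichlet
#' conditions 1 V / 0 V) and returns the potential difference per unit
#' current flowing between them.
#'
#' @inheritParams solve_flow
#' @return Effective resistance (ohms per unit conductance scale).
#' @export
effective_resistance <- function(net, sources, grounds) {
  sources <- as.integer(sources); grounds <- as.integer(grounds)
  if (length(intersect(sources, grounds))) {
    stop("sources and grounds must be disjoint", call. = FALSE)
  }
  comp <- node_components(net)
  if (!any(comp[sources] %in% comp[grounds])) {
    stop("no source shares a component with a ground", call. = FALSE)
  }
  L <- net$laplacian
  n <- net$n_nodes
  v <- numeric(n)
  v[sources] <- 1
  unknown <- setdiff(which(comp %in% comp[grounds] | comp %in% comp[sources]),
                     c(sources, grounds))
  if (length(unknown)) {
    b <- -as.numeric(L[unknown, sources, drop = FALSE] %*% rep(1, length(sources)))
    v[unknown] <- as.numeric(chol_solve(L[unknown, unknown, drop = FALSE], b))
  }
  total <- -sum(as.numeric(L[grounds, , drop = FALSE] %*% v))
  if (total <= 0) stop("no current flows between the node sets", call. = FALSE)
  1 / total
}

#' Strip node ids along one raster edge
#'
#' One-pixel-wide strips along a cardinal edge of the grid, used as
#' wall-to-wall sources and grounds. Masked cells are skipped.
#'
#' @param net An `omc_network`.
#' @param side `"north"`, `"south"`, `"east"` or `"west"`.
#' @return Integer node ids.
#' @export
strip_nodes <- function(net, side = c("north", "south", "east", "west")) {
  side <- match.arg(side)
  ids <- switch(side,
    north = net$node_of[1, ],
    south = net$node_of[net$dims[1], ],
    east  = net$node_of[, net$dims[2]],
    west  = net$node_of[, 1])
  out <- ids[!is.na(ids)]
  if (length(out) == 0L) {
    stop(sprintf("the %s strip is entirely masked", side), call. = FALSE)
  }
  out
}
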