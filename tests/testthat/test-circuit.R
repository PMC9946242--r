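test_that("network construction follows the mean-cost resistor convention", {
  # 1x3 unit strip: two edges, each r = 1
  net <- build_network(cost_raster(matrix(1, 1, 3)), connectivity = 4)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$g, c(1, 1))

  # 1x2 costs (1, 3): single edge r = (1+3)/2 = 2
  net <- build_network(cost_raster(matrix(c(1, 3), 1)))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$g, 0.5)

  # 2x2, 8-connected: 4 orthogonal + 2 diagonal edges, enumerated by hand
  # (column-major node ids: 1=(1,1), 2=(2,1), 3=(1,2), 4=(2,2))
  net <- build_network(cost_raster(matrix(c(1, 2, 3, 4), 2)))
  expect_equal(nrow(net$edges), 6)
  expected_g <- c(1 / ((1 + 2) / 2), 1 / ((3 + 4) / 2),   # vertical pairs
                  1 / ((1 + 3) / 2), 1 / ((2 + 4) / 2),   # horizontal pairs
                  1 / (sqrt(2) * (1 + 4) / 2),            # main diagonal
                  1 / (sqrt(2) * (2 + 3) / 2))            # anti-diagonal
  expect_equal(sort(net$edges$g), sort(expected_g), tolerance = 1e-12)

  expect_error(build_network(cost_raster(matrix(1, 2, 2)), connectivity = 6),
               "4 or 8")
  expect_error(cost_raster(matrix(c(1, -1), 1)), "strictly positive")
})

test_that("series strip solves give linear potentials and unit current", {
  net <- build_network(cost_raster(matrix(1, 1, 5)), connectivity = 4)
  sol <- solve_flow(net, sources = 1, grounds = 5, injections = 1)
  expect_equal(sol$v, c(4, 3, 2, 1, 0), tolerance = 1e-12)
  cur <- node_currents(net, sol)
  expect_equal(as.vector(cur$values), rep(1, 5), tolerance = 1e-12)
  expect_equal(effective_resistance(net, 1, 5), 4, tolerance = 1e-12)
  expect_lt(sol$residual, 1e-10)
})

test_that("parallel disjoint strips split the current evenly", {
  m <- matrix(1, 3, 3); m[2, ] <- NA  # rows 1 and 3 alive, disconnected
  net <- build_network(cost_raster(m))
  src <- net$node_of[c(1, 3), 1]
  gnd <- net$node_of[c(1, 3), 3]
  # each strip has resistance 2; in parallel, 1
  expect_equal(effective_resistance(net, src, gnd), 1, tolerance = 1e-12)
  sol <- solve_flow(net, src, gnd, injections = c(0.5, 0.5))
  cur <- node_currents(net, sol)
  expect_equal(cur$values[1, ], rep(0.5, 3), tolerance = 1e-12)
  expect_equal(cur$values[3, ], rep(0.5, 3), tolerance = 1e-12)
})

test_that("sparse solve matches the dense Laplacian oracle on random landscapes", {
  for (seed in 1:6) {
    set.seed(seed)
    nr <- sample(4:12, 1); nc <- sample(4:12, 1)
    m <- matrix(runif(nr * nc, 1, 100), nr, nc)
    cost <- cost_raster(m)
    net <- build_network(cost)
    src <- net$node_of[1, ]; gnd <- net$node_of[nr, ]
    inj <- rep(1 / nc, nc)
    sol <- solve_flow(net, src, gnd, injections = inj)
    cur <- node_currents(net, sol)
    oracle <- dense_flow_oracle(m, src, gnd, inj)
    expect_lt(max(abs(sol$v - oracle$v)), 1e-6)
    expect_lt(max(abs(as.vector(cur$values) - oracle$current)), 1e-6)
  }
})

test_that("effective resistance matches the pseudo-inverse oracle", {
  set.seed(7)
  m <- matrix(runif(9, 1, 10), 3, 3)
  net <- build_network(cost_raster(m))
  expect_equal(effective_resistance(net, 1, 9),
               dense_reff_oracle(m, 1, 9), tolerance = 1e-8)
  # merged multi-node terminals
  expect_equal(effective_resistance(net, net$node_of[1, ], net$node_of[3, ]),
               dense_reff_oracle(m, net$node_of[1, ], net$node_of[3, ]),
               tolerance = 1e-8)
})

test_that("Kirchhoff current law and cut conservation hold", {
  cost <- fixture_patchy_cost(12, 15, patch = 3, seed = 5)
  net <- build_network(cost)
  src <- strip_nodes(net, "north"); gnd <- strip_nodes(net, "south")
  for (mode in c("hard", "balanced")) {
    sol <- solve_flow(net, src, gnd, total_injection = 1, ground = mode)
    net_in <- as.numeric(net$laplacian %*% sol$v)
    interior <- setdiff(seq_len(net$n_nodes), c(src, gnd))
    expect_lt(max(abs(net_in[interior])), 1e-8)
    # signed flow across every horizontal cut equals the total injection
    rows <- matrix(0L, net$n_nodes, 1)
    row_of <- ((net$cell_of - 1L) %% net$dims[1]) + 1L
    e <- net$edges
    for (cut in 1:(net$dims[1] - 1)) {
      above_i <- row_of[e$i] <= cut; above_j <- row_of[e$j] <= cut
      crossing <- above_i != above_j
      sgn <- ifelse(above_i[crossing], 1, -1)  # + when i is on the source side
      flow <- sum(sgn * e$g[crossing] * (sol$v[e$i[crossing]] - sol$v[e$j[crossing]]))
      expect_equal(flow, 1, tolerance = 1e-8)
    }
  }
})

test_that("scaling all costs leaves the current map unchanged", {
  cost <- fixture_patchy_cost(10, 12, patch = 3, seed = 9)
  net1 <- build_network(cost)
  net2 <- build_network(cost_raster(cost$values * 7.5, cost$cell_size,
                                    cost$origin))
  src <- strip_nodes(net1, "west"); gnd <- strip_nodes(net1, "east")
  c1 <- node_currents(net1, solve_flow(net1, src, gnd))
  c2 <- node_currents(net2, solve_flow(net2, src, gnd))
  expect_equal(c1$values, c2$values, tolerance = 1e-10)
})

test_that("disconnected sources are rejected with a component diagnostic", {
  m <- matrix(1, 3, 3); m[2, ] <- NA
  net <- build_network(cost_raster(m))
  src <- net$node_of[1, 1]; gnd <- net$node_of[3, 3]
  expect_error(solve_flow(net, src, gnd, injections = 1), "component")
  expect_error(solve_flow(net, src, gnd, injections = 1, ground = "balanced"),
               "component|connected")
  expect_error(solve_flow(net, 1, 1, injections = 1), "disjoint")
})
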