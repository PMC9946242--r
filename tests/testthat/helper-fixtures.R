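# Shared fixtures, built in code at test time.

fixture_patchy_cost <- function(nr = 30, nc = 40, patch = 5, seed = 42) {
  land <- generate_patchy_landscape(nr, nc, 1:4, patch, seed = seed)
  combine_layers(list(land), cost_schema())
}

fixture_random_cost <- function(nr, nc, seed) {
  set.seed(seed)
  cost_raster(matrix(stats::runif(nr * nc, 1, 50), nr, nc))
}

rotate90 <- function(m) t(m)[, nrow(m):1]
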