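test_that("patchy landscapes are deterministic, quantized and autocorrelated", {
  a <- generate_patchy_landscape(50, 50, 1:4, 8, seed = 1)
  b <- generate_patchy_landscape(50, 50, 1:4, 8, seed = 1)
  expect_identical(a$values, b$values)
  expect_true(all(a$values %in% 1:4))
  # near-zero patch scale: every category holds ~1/k of the cells
  tiny <- generate_patchy_landscape(60, 60, 1:3, 1e-4, seed = 2)
  freq <- table(tiny$values) / 3600
  expect_true(all(abs(freq - 1 / 3) < 0.05))
  # positive spatial autocorrelation at a meaningful patch scale
  big <- generate_patchy_landscape(60, 60, 1:4, 6, seed = 3)$values
  match_rate <- mean(big[-1, ] == big[-60, ])
  expect_gt(match_rate, 0.8)
  expect_error(generate_patchy_landscape(0, 10, 1:3, 2, seed = 1), "positive")
  expect_error(generate_patchy_landscape(10, 10, 1, 2, seed = 1),
               "at least 2 categories")
})

test_that("split landscapes are exact 50/50 divisions", {
  sl <- generate_split_landscape(4, 1, 100, "vertical")
  expect_equal(sl$values[, 1:2], matrix(1, 4, 2))
  expect_equal(sl$values[, 3:4], matrix(100, 4, 2))
  expect_equal(sum(sl$values == 1), 8)
  expect_equal(sum(sl$values == 100), 8)
  sh <- generate_split_landscape(6, 2, 50, "horizontal")
  expect_equal(unique(as.vector(sh$values[1:3, ])), 2)
  expect_equal(unique(as.vector(sh$values[4:6, ])), 50)
  expect_error(generate_split_landscape(5, 1, 100), "even")
  expect_error(generate_split_landscape(4, 100, 100), "low_cost < high_cost")
})

test_that("unbiased tracks visit cells uniformly; biased tracks prefer current", {
  flat <- current_map(matrix(1, 12, 12))
  # one walker's successive positions are autocorrelated, so uniformity of
  # the stationary law is tested on the final fixes of many independent
  # tracks (uniform start + doubly stochastic kernel => exactly uniform)
  cfg <- track_config(3000, 5, preference_strength = 0, seed = 4)
  tr <- simulate_tracks(flat, cfg)
  last <- dplyr::slice_tail(dplyr::group_by(tr, individual_id), n = 1)
  cells <- cells_at(flat, last$x, last$y)
  counts <- table(factor((cells$col - 1L) * 12L + cells$row, levels = 1:144))
  chi2 <- sum((counts - 3000 / 144)^2 / (3000 / 144))
  # 3 sigma above the chi-square mean with 143 df
  expect_lt(chi2, 143 + 3 * sqrt(2 * 143))
  # biased walk dwells in high-current cells
  cost <- fixture_patchy_cost(25, 25, patch = 4, seed = 6)
  omni <- omnidirectional_current(cost)
  trb <- simulate_tracks(omni, track_config(3, 2000, preference_strength = 2,
                                            seed = 5))
  vals <- extract_current(trb, omni)
  expect_gt(mean(vals), mean(omni$values))
  # determinism and strictly increasing timestamps per individual
  tr2 <- simulate_tracks(omni, track_config(3, 50, 1, seed = 9))
  tr3 <- simulate_tracks(omni, track_config(3, 50, 1, seed = 9))
  expect_identical(tr2, tr3)
  expect_true(all(tapply(tr2$timestamp, tr2$individual_id,
                         function(t) all(diff(as.numeric(t)) > 0))))
  expect_error(simulate_tracks(current_map(matrix(NA_real_, 0, 0)), cfg))
})

test_that("displacement coupling spreads walk lengths and displacement", {
  flat <- current_map(matrix(1, 40, 40))
  cfg <- track_config(6, 200, preference_strength = 0,
                      displacement_coupling = 1, seed = 10)
  tr <- simulate_tracks(flat, cfg)
  lens <- tapply(tr$x, tr$individual_id, length)
  expect_gt(max(lens) / min(lens), 3)  # exp(2) spread, up to rounding
})

test_that("telemetry CSV round-trips", {
  flat <- current_map(matrix(1, 8, 8))
  tr <- simulate_tracks(flat, track_config(2, 20, 0, seed = 11))
  path <- tempfile(fileext = ".csv")
  write_telemetry_csv(tr, path)
  back <- read_telemetry_csv(path)
  expect_equal(back$individual_id, tr$individual_id)
  expect_equal(back$x, tr$x)
  expect_equal(as.numeric(back$timestamp), as.numeric(tr$timestamp))
})

test_that("roadkill counts follow the log-linear intensity", {
  cost <- fixture_patchy_cost(30, 30, patch = 4, seed = 12)
  omni <- omnidirectional_current(cost)
  roads <- features_tbl(cbind(c(2, 28), c(-15, -15)))
  sections <- road_sections(roads, 3)
  k1 <- simulate_roadkill(sections, omni, intercept = 1, slope = 0, seed = 1)
  k2 <- simulate_roadkill(sections, omni, intercept = 1, slope = 0, seed = 1)
  expect_identical(k1, k2)
  # lambda = 0 proxy: all-zero counts
  k0 <- simulate_roadkill(sections, omni, intercept = -745, slope = 0, seed = 2)
  expect_true(all(k0$count == 0))
  # strong slope concentrates counts where current is high
  mc <- section_mean_current(sections, omni)
  ks <- simulate_roadkill(sections, omni, intercept = 0,
                          slope = 4 / stats::sd(mc$mean_current), seed = 3)
  expect_gt(suppressWarnings(stats::cor(ks$count, mc$mean_current,
                                        method = "spearman")), 0)
})

test_that("walker oracle conserves walkers and mirrors uniform symmetry", {
  cost <- cost_raster(matrix(1, 5, 5))
  vis <- random_walk_visits(cost, "north", n_walkers = 20000, seed = 3)
  expect_equal(attr(vis, "absorbed") + attr(vis, "discarded"), 20000)
  counts <- attr(vis, "visits")
  # symmetry about the vertical source-ground axis, within sampling noise
  expect_lt(max(abs(counts - counts[, 5:1])) / max(counts), 0.1)
  # single-walker determinism
  one <- random_walk_visits(cost, "north", n_walkers = 1, seed = 9)
  two <- random_walk_visits(cost, "north", n_walkers = 1, seed = 9)
  expect_identical(one$values, two$values)
})

test_that("walker usage ranks like the directional current map", {
  cost <- fixture_patchy_cost(15, 20, patch = 4, seed = 8)
  vis <- random_walk_visits(cost, "north", n_walkers = 3e4, seed = 21)
  cur <- directional_run(cost, "N-S", ground = "hard")
  rho <- spearman_oracle(as.vector(vis$values), as.vector(cur$values))
  expect_gt(rho, 0.9)
})
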