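test_that("cost schemas enforce rank order and the unit floor", {
  s <- cost_schema()
  expect_equal(s$costs, c(1, 10, 100, 1000))
  expect_error(cost_schema(c(a = 1, b = 1)), "strictly increasing")
  expect_error(cost_schema(c(a = 0.5, b = 2)), ">= 1")
  expect_error(cost_schema(c(a = 1)), "at least 2")
  path <- tempfile(fileext = ".yml")
  writeLines("name: C9\ncosts:\n  low: 1\n  medium_low: 10\n  medium_high: 100\n  high: 1000",
             path)
  s2 <- read_cost_schema(path)
  expect_equal(s2$name, "C9")
  expect_equal(s2$costs, s$costs)
})

test_that("combination takes the highest-cost category and fills gaps with low", {
  schema <- cost_schema()
  a <- category_raster(matrix(c(NA, 3L, NA, NA), 2), 1:4)
  b <- category_raster(matrix(c(NA, 4L, 2L, NA), 2), 1:4)
  cost <- combine_layers(list(a, b), schema)
  # cell 2: medium-high vs high -> high; cell 3: medium-low; empty cells -> low
  expect_equal(as.vector(cost$values), c(1, 1000, 10, 1))
  # single all-nodata layer -> uniform low
  empty <- category_raster(matrix(NA_integer_, 3, 3), 1:4)
  expect_equal(unique(as.vector(combine_layers(list(empty), schema)$values)), 1)
  # misaligned grids rejected
  shifted <- category_raster(matrix(1L, 2, 2), 1:4, origin = c(5, 0))
  expect_error(combine_layers(list(a, shifted), schema), "misaligned")
})

test_that("combination is idempotent, order-invariant and monotone", {
  schema <- cost_schema()
  set.seed(21)
  layers <- lapply(1:4, function(i) {
    v <- matrix(sample(c(NA, 1:4), 30, replace = TRUE), 5, 6)
    category_raster(v, 1:4)
  })
  combined <- combine_layers(layers, schema)
  expect_true(all(combined$values %in% schema$costs))
  # order invariance
  expect_equal(combine_layers(rev(layers), schema)$values, combined$values)
  # idempotence: re-expressing the result as a layer and recombining changes nothing
  again <- combine_layers(c(layers, list(cost_to_categories(combined, schema))),
                          schema)
  expect_equal(again$values, combined$values)
  # monotonicity: an extra layer can only raise costs
  extra <- category_raster(matrix(sample(c(NA, 1:4), 30, replace = TRUE), 5, 6), 1:4)
  more <- combine_layers(c(layers, list(extra)), schema)
  expect_true(all(more$values >= combined$values))
})

test_that("resampling is identity on the target grid and modal on blocks", {
  target <- cost_raster(matrix(1, 4, 4), cell_size = 2)
  fine_vals <- matrix(sample(1:4, 64, replace = TRUE), 8, 8)
  fine <- category_raster(fine_vals, 1:4, cell_size = 1)
  same <- category_raster(matrix(1L, 4, 4), 1:4, cell_size = 2)
  expect_identical(resample_layer(same, target, "nearest"), same)
  modal <- resample_layer(fine, target, "mode")
  expect_equal(unname(modal$values), block_mode_oracle(fine_vals, 2, 2))
  cont <- cost_raster(matrix(runif(64, 1, 2), 8, 8))
  expect_error(resample_layer(cont, target, "mode"), "category")
  far <- category_raster(matrix(1L, 2, 2), 1:4, origin = c(100, 100))
  expect_error(resample_layer(far, target, "nearest"), "overlap")
})

test_that("polyline rasterization is any-touch, verified per cell", {
  grid <- cost_raster(matrix(1, 10, 10), cell_size = 1, origin = c(0, 10))
  # horizontal line through row 3 (y = 7.4), x from 1.2 to 8.7
  feats <- features_tbl(cbind(c(1.2, 8.7), c(7.4, 7.4)))
  ras <- rasterize_features(feats, grid, "high")
  hit <- which(!is.na(ras$values), arr.ind = TRUE)
  expect_true(all(hit[, "row"] == 3))
  expect_equal(sort(hit[, "col"]), 2:9)
  # oracle check on a random diagonal segment
  set.seed(4)
  p <- runif(2, 0, 10); q <- runif(2, 0, 10)
  ras2 <- rasterize_features(features_tbl(rbind(p, q)), grid, "high")
  for (r in 1:10) {
    for (cc in 1:10) {
      ora <- segment_hits_cell_oracle(p, q, cc - 1, cc, 10 - r, 10 - r + 1)
      expect_equal(!is.na(ras2$values[r, cc]), ora,
                   label = sprintf("cell (%d,%d)", r, cc))
    }
  }
  # polygon covering the whole grid -> all cells; outside extent -> none
  poly <- features_tbl(rbind(c(-1, -1), c(11, -1), c(11, 11), c(-1, 11)),
                       type = "Polygon")
  expect_true(all(!is.na(rasterize_features(poly, grid, "high")$values)))
  off <- features_tbl(cbind(c(20, 30), c(20, 20)))
  expect_true(all(is.na(rasterize_features(off, grid, "high")$values)))
  expect_true(all(is.na(rasterize_features(feats[0, ], grid, "high")$values)))
})

test_that("natural thresholds use the printed comparison operators", {
  grid <- cost_raster(matrix(1, 5, 5), cell_size = 1, origin = c(0, 5))
  elev <- cost_raster(matrix(100, 5, 5), cell_size = 1, origin = c(0, 5))
  elev$values[2, 2] <- 2301
  elev$values[3, 3] <- 2300  # boundary: strictly greater only
  slope <- cost_raster(matrix(1e-9, 5, 5), cell_size = 1, origin = c(0, 5))
  lakes <- features_tbl(
    list(rbind(c(0.1, 4.9), c(1.9, 4.9), c(1.9, 3.1), c(0.1, 3.1)),
         rbind(c(3.1, 1.9), c(4.9, 1.9), c(4.9, 0.1), c(3.1, 0.1))),
    type = "Polygon", area_ha = c(9.99, 10))
  layers <- suppressWarnings(apply_natural_thresholds(
    grid, elevation = elev, slope = slope, lakes = lakes,
    rivers = NULL, sea_ice = NULL))
  expect_equal(sum(!is.na(layers$elevation$values)), 1)
  expect_equal(layers$elevation$values[2, 2], 4L)
  expect_true(all(is.na(layers$slope$values)))
  # the 9.99 ha lake is excluded; the 10 ha lake (>= cutoff) is burned
  lake_cells <- which(!is.na(layers$lakes$values), arr.ind = TRUE)
  expect_true(all(lake_cells[, "row"] >= 4 & lake_cells[, "col"] >= 4))
  expect_gt(nrow(lake_cells), 0)
  w <- capture_warnings(apply_natural_thresholds(grid, elevation = elev,
                                                 slope = slope, lakes = lakes,
                                                 rivers = NULL,
                                                 sea_ice = NULL))
  expect_true(any(grepl("rivers", w)))
  expect_true(any(grepl("sea-ice", w)))
})
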