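test_that("observed subsampling takes the stated fraction, reproducibly", {
  tr <- tibble::tibble(timestamp = 1:100, x = runif(100), y = runif(100))
  s1 <- subsample_observed(tr, 0.1, seed = 3)
  expect_equal(nrow(s1), 10)
  expect_identical(s1, subsample_observed(tr, 0.1, seed = 3))
  expect_equal(nrow(subsample_observed(tr, 1.0, seed = 1)), 100)
  expect_error(subsample_observed(tr, 0), "fraction")
  expect_error(subsample_observed(tr[0, ], 0.5), "empty")
})

test_that("maximum displacement is anchored at the earliest fix", {
  tr <- tibble::tibble(timestamp = c(1, 2, 3), x = c(0, 3, 1), y = c(0, 4, 1))
  expect_equal(max_displacement(tr), 5)
  # anchor follows time order, not row order
  tr2 <- tr[c(2, 1, 3), ]
  expect_equal(max_displacement(tr2), 5)
  same <- tibble::tibble(timestamp = 1:3, x = rep(2, 3), y = rep(2, 3))
  expect_equal(max_displacement(same), 0)
  expect_warning(max_displacement(same[1, ]), "single point")
  long <- tibble::tibble(timestamp = 1:4, x = c(0, 9, 2, 1), y = rep(0, 4))
  expect_gte(max_displacement(long),
             sqrt((long$x[4] - long$x[1])^2 + (long$y[4] - long$y[1])^2))
})

test_that("the UD mask contains the isopleth mass and honours symmetry", {
  grid <- current_map(matrix(1, 30, 30), cell_size = 1, origin = c(0, 30))
  set.seed(5)
  pts <- tibble::tibble(x = rnorm(60, 15, 3), y = rnorm(60, 15, 3))
  mask <- kernel_ud(pts, grid, 0.95)
  D <- attr(mask, "density")
  mass <- sum(D[mask])
  expect_gte(mass, 0.95)
  # minimality up to ties: removing the threshold-density cells drops the
  # mass below the isopleth
  thresh_cells <- mask & (D <= min(D[mask]) + 1e-15)
  expect_lt(mass - sum(D[thresh_cells]), 0.95)
  # isopleth 1 keeps every positive-density cell
  m1 <- kernel_ud(pts, grid, 1.0)
  expect_true(all(m1[D > 1e-300]))
  # two symmetric clusters give a symmetric mask
  sym <- tibble::tibble(x = c(rep(10, 10), rep(20, 10)),
                        y = rep(c(8, 10, 12, 14, 16), 4))
  ms <- kernel_ud(sym, grid, 0.9)
  expect_equal(unname(ms), unname(ms[, 30:1]), ignore_attr = TRUE)
  co <- tibble::tibble(x = rep(4.5, 6), y = rep(7.5, 6))
  expect_warning(mco <- kernel_ud(co, grid), "coincident")
  expect_equal(sum(mco), 1)
})

test_that("available sampling stays in the dilated region, which grows with d_max", {
  grid <- current_map(matrix(1, 20, 20), cell_size = 1, origin = c(0, 20))
  mask <- matrix(FALSE, 20, 20); mask[9:12, 9:12] <- TRUE
  pts <- sample_available(mask, d_max = 0, n = 200, grid, seed = 2)
  cells <- cells_at(grid, pts$x, pts$y)
  expect_true(all(mask[cbind(cells$row, cells$col)]))
  areas <- vapply(c(0, 2, 4, 6), function(d) {
    sum(omnicurrent:::dilate_mask(mask, d))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  pts2 <- sample_available(mask, d_max = 3, n = 300, grid, seed = 3)
  cells2 <- cells_at(grid, pts2$x, pts2$y)
  dil <- omnicurrent:::dilate_mask(mask, 3)
  expect_true(all(dil[cbind(cells2$row, cells2$col)]))
  expect_error(sample_available(matrix(FALSE, 3, 3), 0, 5,
                                current_map(matrix(1, 3, 3))), "empty")
})

test_that("current extraction honours the buffer radius at 300 m cells", {
  vals <- matrix(1:25 + 0.0, 5, 5)
  cur <- current_map(vals, cell_size = 300, origin = c(0, 1500))
  centers <- cell_centers(cur)
  p <- centers[centers$row == 3 & centers$col == 3, ]
  expect_equal(extract_current(p, cur), vals[3, 3])
  # 300 m radius: focal cell + the four orthogonal neighbours (at exactly 300 m)
  v300 <- extract_current(p, cur, buffer_radius = 300)
  expect_equal(v300, mean(c(vals[3, 3], vals[2, 3], vals[4, 3],
                            vals[3, 2], vals[3, 4])))
  # uniform map: radius does not matter
  uni <- current_map(matrix(7, 5, 5), cell_size = 300, origin = c(0, 1500))
  expect_equal(extract_current(p, uni, 450), 7)
  off <- tibble::tibble(x = -100, y = 200)
  expect_warning(res <- extract_current(off, cur), "outside")
  expect_equal(length(res), 0)
})

test_that("quartile bins split movers by rank only", {
  cls <- quartile_bins(1:8)
  expect_equal(as.character(cls[1:2]), c("short", "short"))
  expect_equal(as.character(cls[7:8]), c("long", "long"))
  expect_true(all(cls[3:6] == "middle"))
  # invariant to strictly increasing transforms
  expect_equal(quartile_bins(exp(1:8)), cls)
  four <- quartile_bins(c(3, 1, 9, 5))
  expect_equal(as.character(four), c("middle", "short", "long", "middle"))
  expect_warning(all_mid <- quartile_bins(rep(2, 6)), "equal")
  expect_true(all(all_mid == "middle"))
  expect_error(quartile_bins(1:3), "at least 4")
})

test_that("the point t-test matches hand computations", {
  res <- point_ttest(c(0, 2), c(1, 3))
  expect_equal(res$cohens_d, -1 / sqrt(2), tolerance = 1e-12)
  expect_equal(res$t, welch_t_oracle(c(0, 2), c(1, 3)), tolerance = 1e-10)
  set.seed(8)
  a <- rnorm(30); b <- rnorm(25, 0.3)
  res2 <- point_ttest(a, b)
  expect_equal(res2$t, welch_t_oracle(a, b), tolerance = 1e-10)
  # one-sided p agrees with the upper-tail t probability
  expect_equal(res2$p, stats::pt(res2$t, res2$df, lower.tail = FALSE),
               tolerance = 1e-10)
  same <- point_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$cohens_d, 0)
  expect_warning(point_ttest(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("case models recover known effects and report Wald intervals", {
  set.seed(14)
  n_id <- 20; n_pt <- 15
  make_data <- function(effect_fun) {
    purrr::map_dfr(seq_len(n_id), function(i) {
      dmax <- runif(1, 1, 10)
      mu <- rnorm(1, 5, 0.5)
      tibble::tibble(
        individual_id = sprintf("i%02d", i),
        case = rep(c(1L, 0L), each = n_pt),
        current_value = mu + effect_fun(dmax) * rep(c(1, 0), each = n_pt) +
          rnorm(2 * n_pt, 0, 0.1),
        d_max = dmax
      )
    })
  }
  d1 <- make_data(function(d) 1)
  f1 <- fit_case_model(d1)
  ci <- tidy(f1)[tidy(f1)$term == "case", ]
  expect_gt(ci$estimate, 0.9); expect_lt(ci$estimate, 1.1)
  expect_true(ci$conf_low <= 1 && 1 <= ci$conf_high)
  g <- glance(f1)
  expect_equal(g$n_individuals, n_id)
  expect_equal(g$n_obs, n_id * 2 * n_pt)
  # interaction recovery: gap = 0.1 * d_max
  d2 <- make_data(function(d) 0.1 * d)
  f2 <- fit_interaction_model(d2)
  co <- tidy(f2)
  inter <- co[co$term == "case:d_max", ]
  expect_true(inter$conf_low <= 0.1 && 0.1 <= inter$conf_high)
  # constant effect: interaction CI covers 0
  f3 <- fit_interaction_model(d1)
  co3 <- tidy(f3); i3 <- co3[co3$term == "case:d_max", ]
  expect_true(i3$conf_low <= 0 && 0 <= i3$conf_high)
  # predicted difference at d = 0 equals the case main effect
  pred <- predict_case_difference(f2, c(0, 5))
  expect_equal(pred$difference[1],
               co$estimate[co$term == "case"], tolerance = 1e-12)
  # degenerate response: zero case effect, reported not dropped
  d0 <- d1; d0$current_value <- 1
  f0 <- fit_case_model(d0)
  expect_equal(tidy(f0)$estimate[tidy(f0)$term == "case"], 0, tolerance = 1e-10)
  expect_true(all(is.finite(tidy(f0)$std_error)))
  expect_equal(f0$ranef_variance, 0)
  expect_error(fit_case_model(d1[d1$case == 1, ]), "both")
  expect_error(fit_interaction_model(dplyr::mutate(d1, d_max = 1)), "vary")
})

test_that("permuting case labels within individuals mostly covers zero", {
  set.seed(15)
  cover <- 0
  base <- purrr::map_dfr(1:15, function(i) {
    tibble::tibble(individual_id = sprintf("i%02d", i),
                   case = rep(c(1L, 0L), each = 12),
                   current_value = rnorm(1, 5) + rnorm(24, 0, 0.5),
                   d_max = runif(1, 1, 5))
  })
  for (rep in 1:20) {
    perm <- dplyr::group_by(base, .data$individual_id)
    perm <- dplyr::mutate(perm, case = sample(.data$case))
    fit <- suppressMessages(fit_case_model(dplyr::ungroup(perm)))
    ci <- tidy(fit)[tidy(fit)$term == "case", ]
    cover <- cover + (ci$conf_low <= 0 && 0 <= ci$conf_high)
  }
  expect_gte(cover, 18)
})
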