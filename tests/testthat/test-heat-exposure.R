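test_that("heat index matches the published regression and its domain", {
  expect_equal(round(heat_index(90, 50), 2), 94.60)
  expect_true(is.na(heat_index(75, 60)))   # below the 80 F validity domain
  expect_error(heat_index(90, 101), "humidity")
  expect_error(heat_index(90, -1), "humidity")
})

test_that("heat index is monotone in humidity on the valid domain", {
  for (t in seq(80, 100, by = 2)) {
    rh <- seq(40, 100, by = 1)
    expect_true(all(diff(heat_index(t, rh)) >= 0), label = paste("t =", t))
  }
})

test_that("heat index agrees with an independent evaluation to 1e-9", {
  grid <- expand.grid(t = seq(80, 106, by = 0.5), rh = seq(0, 100, by = 1))
  expect_equal(heat_index(grid$t, grid$rh), hi_oracle(grid$t, grid$rh),
               tolerance = 1e-12)
  expect_lt(max(abs(heat_index(grid$t, grid$rh) -
                      hi_oracle(grid$t, grid$rh))), 1e-9)
})

test_that("heat-index categories follow the published bins", {
  expect_equal(categorize_hi(86), "hot")
  expect_equal(categorize_hi(c(84, 85)), c("moderate", "hot"))
  expect_equal(categorize_hi(93), "very_hot")
  expect_equal(categorize_hi(c(80, 92, 106)),
               c("moderate", "hot", "very_hot"))
  expect_error(categorize_hi(107), "calibration")
  expect_error(categorize_hi(NA_real_), "80")
  # idempotent under rounding: the label of a rounded value is unchanged
  x <- c(80.2, 84.5, 92.4, 93.49)
  expect_equal(categorize_hi(round(x)), categorize_hi(x))
})

test_that("minimum-temperature categories follow the published bins", {
  expect_equal(categorize_min_temp(45, 60), "cool")
  expect_equal(categorize_min_temp(55, 70), "baseline")
  expect_equal(categorize_min_temp(c(9, 10), c(30, 30)),
               c("very_cold", "cold"))
  expect_equal(categorize_min_temp(55, 85), "hi_axis")
  expect_error(categorize_min_temp(-18, 10), "calibration")
})

test_that("exposure assignment partitions plant-weeks exhaustively", {
  set.seed(21)
  n <- 4000
  t_avg <- runif(n, -10, 100)
  t_min <- t_avg - runif(n, 2, 25)
  rh <- runif(n, 0, 100)
  e <- assign_exposure(t_avg, t_min, rh)
  expect_true(all(e$axis %in% c("hi", "min_temp", "baseline", "excluded")))
  # every excluded row has a reason, every modelled row a category
  expect_true(all(!is.na(e$reason[e$axis == "excluded"])))
  expect_true(all(is.na(e$reason[e$axis != "excluded"])))
  expect_true(all(!is.na(e$category[e$axis != "excluded"])))
  # labels match the axis
  expect_true(all(e$category[e$axis == "hi"] %in%
                    c("moderate", "hot", "very_hot")))
  expect_true(all(e$category[e$axis == "min_temp"] %in%
                    c("cool", "cold", "very_cold")))
  # assignment is deterministic and order-independent
  o <- sample(n)
  e2 <- assign_exposure(t_avg[o], t_min[o], rh[o])
  expect_equal(e2$category, e$category[o])
})

test_that("offset spline recovers a flat condemnation rate", {
  set.seed(23)
  n <- 2000
  x <- runif(n, 50, 100)
  total <- sample(200:5000, n, replace = TRUE)
  y <- rpois(n, total * 0.003)
  fit <- fit_offset_spline(x, y, total)
  expect_true(all(fit$intensity >= 0))
  expect_lt(max(abs(fit$intensity - 0.003)) / 0.003, 0.05)
})

test_that("offset spline localizes a step in the rate", {
  set.seed(23)
  n <- 5000
  x <- runif(n, 60, 100)
  total <- sample(500:5000, n, replace = TRUE)
  rate <- ifelse(x > 85, 0.004, 0.002)
  y <- rpois(n, total * rate)
  fit <- fit_offset_spline(x, y, total)
  d1 <- predict(fit$smooth, fit$grid, deriv = 1)$y
  expect_lt(abs(fit$grid[which.max(d1)] - 85), 2)
  # the same jump drives the suggested cutpoint
  bp <- suggest_breakpoints(fit, 1)
  expect_lt(abs(bp - 85), 2)
})

test_that("head-count weights pull the spline toward the heavier subset", {
  x <- rep(seq(60, 90, length.out = 40), 2)
  total <- c(rep(1000, 40), rep(1000, 40))
  y <- c(1000 * 0.002 * rep(1, 40), 1000 * 0.006 * rep(1, 40))
  f_eq <- fit_offset_spline(x, y, total, smoothing = 1)
  total2 <- c(rep(1000, 40), rep(2000, 40))
  y2 <- c(1000 * 0.002 * rep(1, 40), 2000 * 0.006 * rep(1, 40))
  f_up <- fit_offset_spline(x, y2, total2, smoothing = 1)
  expect_gt(mean(f_up$intensity), mean(f_eq$intensity))
  expect_equal(mean(f_eq$intensity), 0.004, tolerance = 1e-6)
})

test_that("spline explorer rejects degenerate inputs and k", {
  expect_error(fit_offset_spline(rep(70, 50), rpois(50, 1), rep(100, 50)),
               "distinct")
  expect_error(fit_offset_spline(runif(50, 60, 90), rpois(50, 1),
                                 rep(0, 50)), "total")
  set.seed(24)
  x <- runif(500, 50, 100)
  total <- rep(1000, 500)
  # exactly constant rate: a no-signal curve
  flat <- fit_offset_spline(x, total * 0.003, total, smoothing = 1)
  expect_error(suggest_breakpoints(flat, 0), "k")
  expect_error(suggest_breakpoints(flat, 10000), "grid")
  bp <- suggest_breakpoints(flat, 3)
  expect_equal(bp, unname(quantile(flat$grid, c(0.25, 0.5, 0.75))))
})
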