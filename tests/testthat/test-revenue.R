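test_that("baseline model recovers class rates absent temperature effects", {
  # small random-intercept SD: with only five volume groups, one realized
  # draw of the group effects shifts every population-level rate by
  # exp(mean u), so rate recovery is only sharp when that shift is small
  # high head counts and mild overdispersion so the generating rates are
  # estimable to well under the 5% band
  s <- sim_revenue_data(10000, 0, seed = 51, sigma_u = 0.02, pi = 0.2,
                        theta = 5)
  f <- fit_baseline_model(s$base)
  expect_true(f$converged)
  for (cl in c("market", "cull_sow", "roaster")) {
    truth <- c(market = 0.0030, cull_sow = 0.0027, roaster = 0.00123)[[cl]]
    expect_lt(abs(predict_rate(f, cl) - truth) / truth, 0.05, label = cl)
  }
  # the baseline fit never sees exposure columns: permuting them changes
  # nothing
  s2 <- s$base
  s2$category <- sample(s2$category)
  f2 <- fit_baseline_model(s2)
  expect_equal(f2$beta, f$beta)
})

test_that("a class with no baseline weeks is reported by name", {
  s <- sim_revenue_data(300, 100, seed = 52)
  s$base <- s$base[s$base$class != "roaster", ]
  expect_error(fit_baseline_model(dplyr::bind_rows(s$base, s$ext)),
               "roaster")
})

test_that("excess is the signed residual observed minus expected", {
  s <- sim_revenue_data(2000, 300, seed = 53)
  f <- fit_baseline_model(s$base)
  led <- excess_condemnations(f, s$ext)
  expect_equal(led$excess, led$observed - led$expected, tolerance = 1e-12)
  expect_equal(led$observed, s$ext$condemned)
  # conditional expectation uses the group's random-effect mode
  exp_manual <- (1 - f$pi) *
    exp(unname(f$beta[paste0(s$ext$class)]) + log(s$ext$total) +
          unname(f$u_hat[s$ext$volume_category]))
  expect_equal(led$expected, exp_manual, tolerance = 1e-12)
  # missing volume category errors
  bad <- s$ext
  bad$volume_category[1] <- NA
  expect_error(excess_condemnations(f, bad), "volume")
})

test_that("attributed excess matches the generating multiplier", {
  s <- sim_revenue_data(5000, 5000, seed = 54, multiplier = 1.37)
  f <- fit_baseline_model(s$base)
  led <- excess_condemnations(f, s$ext)
  expect_lt(abs(sum(led$excess) - 0.37 * sum(led$expected)) /
              (0.37 * sum(led$expected)), 0.10)
})

test_that("pricing follows the monthly series and the roaster carcass rule", {
  led <- tibble::tibble(
    plant_id = "P1", week = "2013-W28", year = 2013L, month = 7L,
    class = c("market", "roaster", "cull_sow"),
    axis = "hi", category = "hot", total = c(10000, 500, 800),
    observed = c(14, 11, 3), expected = c(10, 1, 3),
    excess = c(4, 10, 0))
  prices <- tibble::tibble(
    year = 2013L, month = 7L, class = c("market", "cull_sow"),
    price_per_head = c(180, 70), dressed_price_per_cwt = c(80, NA))
  out <- price_condemnations(led, prices)
  expect_equal(out$foregone_usd[out$class == "market"], 4 * 180)   # $720
  expect_equal(out$foregone_usd[out$class == "roaster"],
               10 * (70 / 100 * 80))                               # $560
  expect_equal(out$foregone_usd[out$class == "cull_sow"], 0)
  # missing month is an error listing the gap
  expect_error(price_condemnations(transform(led, month = 8L), prices),
               "2013-08")
})

test_that("ledger summaries conserve excess and scale linearly in price", {
  s <- sim_revenue_data(2000, 600, seed = 55)
  f <- fit_baseline_model(s$base)
  led <- excess_condemnations(f, s$ext)
  pm <- tidyr::expand_grid(year = 2013:2014, month = 1:12)
  prices <- dplyr::bind_rows(
    tibble::tibble(year = pm$year, month = pm$month, class = "market",
                   price_per_head = 150, dressed_price_per_cwt = 75),
    tibble::tibble(year = pm$year, month = pm$month, class = "cull_sow",
                   price_per_head = 60, dressed_price_per_cwt = NA))
  priced <- price_condemnations(led, prices)
  summ <- summarize_ledger(priced)
  # conservation: category sums of row-level excess match exactly
  for (cl in unique(priced$class)) {
    expect_equal(summ$increased[summ$class == cl & summ$category == "hot"],
                 sum(priced$excess[priced$class == cl]), tolerance = 1e-12)
  }
  # percent column definition, checked against the published worked example
  demo <- summarize_ledger(tibble::tibble(
    class = "roaster", axis = "min_temp", category = "very_cold",
    excess = 260, foregone_usd = 14600, total = 134000))
  expect_equal(demo$percent, rep(260 / 134000 * 100, 2))
  expect_equal(round(demo$percent[1], 3), 0.194)
  # pricing linearity
  prices2 <- dplyr::mutate(prices, price_per_head = price_per_head * 2,
                           dressed_price_per_cwt = dressed_price_per_cwt * 2)
  summ2 <- summarize_ledger(price_condemnations(led, prices2))
  expect_equal(summ2$foregone_usd_k, summ$foregone_usd_k * 2,
               tolerance = 1e-12)
  expect_equal(summ2$increased, summ$increased)
})
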