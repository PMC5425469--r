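test_that("zinb pmf matches closed forms and an independent density", {
  # closed form: 0.2 + 0.8 * (1/2)^1
  expect_equal(dzinb(0, mu = 1, theta = 1, pi = 0.2), 0.6, tolerance = 1e-12)
  grid <- expand.grid(y = c(0, 1, 3, 17), mu = c(0.3, 2, 40),
                      theta = c(0.5, 1.5, 5), pi = c(0, 0.3, 0.6))
  got <- mapply(function(y, mu, th, pi) dzinb(y, mu, th, pi),
                grid$y, grid$mu, grid$theta, grid$pi)
  ref <- dzinb_oracle(grid$y, grid$mu, grid$theta, grid$pi)
  expect_equal(got, ref, tolerance = 1e-12)
  expect_error(dzinb(-1, 1, 1, 0), "non-negative")
  expect_error(dzinb(0, 1, -1, 0), "theta")
  expect_error(dzinb(0, 1, 1, 1), "pi")
})

test_that("zinb pmf normalizes across the parameter grid", {
  y <- 0:10000
  for (mu in c(0.1, 1, 10, 100)) for (theta in c(0.5, 1, 5))
    for (pi in c(0, 0.3, 0.6)) {
      expect_equal(sum(dzinb(y, mu, theta, pi)), 1, tolerance = 1e-8,
                   label = sprintf("mu=%g theta=%g pi=%g", mu, theta, pi))
    }
})

test_that("zinb approaches the Poisson limit at large dispersion", {
  expect_equal(dzinb(3, mu = 3, theta = 1e6, pi = 0), dpois(3, 3),
               tolerance = 1e-4)
})

test_that("intercept-only degenerate fit equals the closed-form rate MLE", {
  set.seed(31)
  n <- 2000
  N <- sample(50:500, n, replace = TRUE)
  y <- rpois(n, N * 0.003)
  d <- tibble::tibble(condemned = y, total = N, volume_category = "M",
                      class = "market")
  f <- fit_zinb_glmm(d, zero_inflation = FALSE, random_effect = FALSE)
  expect_true(f$converged)
  expect_equal(unname(f$beta), log(sum(y) / sum(N)), tolerance = 1e-3)
})

test_that("degenerate submodel reproduces an independent NB regression", {
  set.seed(32)
  n <- 3000
  N <- sample(100:3000, n, replace = TRUE)
  cls <- sample(c("market", "cull_sow"), n, replace = TRUE)
  cat2 <- sample(c("baseline", "hot"), n, replace = TRUE)
  lr <- ifelse(cls == "market", log(0.003), log(0.0027)) +
    ifelse(cat2 == "hot", log(1.4), 0)
  y <- rnbinom(n, mu = N * exp(lr), size = 2)
  d <- tibble::tibble(condemned = y, total = N, class = cls,
                      category = cat2, volume_category = "M")
  f <- fit_zinb_glmm(d, category_col = "category", zero_inflation = FALSE,
                     random_effect = FALSE)
  ref <- MASS::glm.nb(
    y ~ 0 + cls + cls:hot + offset(log(N)),
    data = data.frame(y = y, cls = factor(cls),
                      hot = as.numeric(cat2 == "hot"), N = N))
  rc <- coef(ref)[c("clscull_sow", "clsmarket", "clscull_sow:hot",
                    "clsmarket:hot")]
  expect_true(f$converged)
  expect_equal(unname(f$beta), unname(rc), tolerance = 1e-3)
  expect_equal(f$theta, ref$theta, tolerance = 0.02)
})

test_that("full mixed-model fit agrees with an independent implementation", {
  skip_if_not_installed("glmmTMB")
  sim <- sim_zinb_records(3000, seed = 33, rates = axis_rates("hi"),
                          theta = 1.5, pi = 0.45, sigma_u = 0.3)
  d <- sim$data
  f <- fit_zinb_glmm(d, category_col = "category", quad_points = 15)
  ref <- glmmTMB::glmmTMB(
    condemned ~ 0 + class + class:catx + (1 | volume_category),
    offset = log(d$total), ziformula = ~1, family = glmmTMB::nbinom2,
    data = transform(d, catx = relevel(factor(category), "baseline")))
  fe <- glmmTMB::fixef(ref)$cond
  # match our term order: class baselines then class:category
  ours <- f$beta
  theirs <- setNames(rep(NA_real_, length(ours)), names(ours))
  for (nm in names(ours)) {
    if (grepl(":", nm)) {
      parts <- strsplit(nm, ":")[[1]]
      theirs[nm] <- fe[paste0("class", parts[1], ":catx", parts[2])]
    } else {
      theirs[nm] <- fe[paste0("class", nm)]
    }
  }
  expect_true(f$converged)
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
  expect_equal(f$theta, glmmTMB::sigma(ref), tolerance = 0.05)
  expect_equal(f$pi, plogis(glmmTMB::fixef(ref)$zi[[1]]), tolerance = 0.02)
})

test_that("parameter recovery at the study-scale simulation", {
  rates <- axis_rates("hi")
  # enough head per class x category cell that every generating rate is
  # estimable to a few percent
  sim <- sim_zinb_records(12000, seed = 34, rates = rates, theta = 1.5,
                          pi = 0.45, sigma_u = 0.3,
                          head_range = c(500, 5000))
  f <- fit_zinb_glmm(sim$data, category_col = "category")
  expect_true(f$converged)
  truth <- vapply(seq_len(nrow(f$design)), function(i) {
    cl <- f$design$class[i]; ct <- f$design$category[i]
    if (ct == "baseline") {
      log(rates$cr[rates$class == cl & rates$category == "baseline"] / 0.55)
    } else {
      log(rates$cr[rates$class == cl & rates$category == ct] /
            rates$cr[rates$class == cl & rates$category == "baseline"])
    }
  }, numeric(1))
  z <- abs(f$beta - truth) / f$se_beta
  expect_true(all(z < 3), info = paste(round(z, 2), collapse = ", "))

  # quadrature self-consistency: the marginal log-likelihood is stable
  ll15 <- zinb_loglik(f, quad_points = 15)
  ll31 <- zinb_loglik(f, quad_points = 31)
  expect_lt(abs(ll31 - ll15) / nrow(sim$data), 1e-4)

  # predicted per-head rates recover the generating rates within 10%
  for (i in seq_len(nrow(rates))) {
    cr <- predict_rate(f, rates$class[i], rates$category[i])
    expect_lt(abs(cr - rates$cr[i]) / rates$cr[i], 0.10,
              label = paste(rates$class[i], rates$category[i]))
  }
})

test_that("condemnation rate is per head: offset rescaling cancels", {
  set.seed(35)
  n <- 1500
  N <- sample(100:1000, n, replace = TRUE)
  y <- rnbinom(n, mu = N * 0.0030, size = 2)
  base <- tibble::tibble(condemned = y, total = N, class = "market",
                         volume_category = "M")
  f1 <- fit_zinb_glmm(base, zero_inflation = FALSE, random_effect = FALSE)
  f2 <- fit_zinb_glmm(transform(base, total = total * 10),
                      zero_inflation = FALSE, random_effect = FALSE)
  r1 <- predict_rate(f1, "market")
  expect_equal(r1, predict_rate(f2, "market") * 10, tolerance = 1e-6)
  # construction: with pi = 0 the rate is exp(beta)
  expect_equal(r1, exp(unname(f1$beta)), tolerance = 1e-12)
})

test_that("singular designs are rejected with the aliased column named", {
  d <- tibble::tibble(condemned = rpois(50, 1), total = 100,
                      class = "market", category = "baseline",
                      volume_category = rep(c("S", "M"), 25))
  d2 <- d
  d2$class <- c(rep("market", 50))
  d2$category <- c(rep("hot", 50))  # class baseline never observed
  expect_error(
    fit_zinb_glmm(d2, category_col = "category"), "aliased|rank")
})

test_that("Wald intervals for beta attain nominal coverage", {
  rates <- tibble::tibble(class = "market",
                          category = c("baseline", "hot"),
                          cr = c(0.0030, 0.0041))
  reps <- 100
  hits <- matrix(NA, reps, 2)
  for (r in seq_len(reps)) {
    sim <- sim_zinb_records(2000, seed = 5000 + r, rates = rates,
                            theta = 1.5, pi = 0.45, sigma_u = 0.3)
    f <- try(fit_zinb_glmm(sim$data, category_col = "category",
                           quad_points = 7), silent = TRUE)
    if (inherits(f, "try-error") || !f$converged) next
    truth <- c(log(0.0030 / 0.55), log(0.0041 / 0.0030))
    hits[r, ] <- abs(f$beta[c("market", "market:hot")] - truth) <
      qnorm(0.975) * f$se_beta[c("market", "market:hot")]
  }
  cover <- colMeans(hits, na.rm = TRUE)
  expect_gt(mean(!is.na(hits[, 1])), 0.95)   # fits almost always converge
  expect_true(all(cover >= 0.90 & cover <= 0.99),
              info = paste(round(cover, 3), collapse = ", "))
})
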