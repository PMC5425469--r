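# Independent oracles and simulation helpers shared across tests.

# Independently coded evaluation of the NWS apparent-temperature regression
# (coefficient vector + term matrix, rather than the package's inline
# polynomial), including both humidity adjustments.
hi_oracle <- function(t, rh) {
  co <- c(-42.379, 2.04901523, 10.14333127, -0.22475541, -6.83783e-3,
          -5.481717e-2, 1.22874e-3, 8.5282e-4, -1.99e-6)
  tm <- cbind(1, t, rh, t * rh, t^2, rh^2, t^2 * rh, t * rh^2, t^2 * rh^2)
  v <- drop(tm %*% co)
  low <- rh < 13 & t >= 80 & t <= 112
  v[low] <- v[low] - ((13 - rh[low]) / 4) * sqrt((17 - abs(t[low] - 95)) / 17)
  high <- rh > 85 & t >= 80 & t <= 87
  v[high] <- v[high] + ((rh[high] - 85) / 10) * ((87 - t[high]) / 5)
  v[t < 80] <- NA_real_
  v
}

# ZINB pmf through stats::dnbinom, independent of the compiled kernel.
dzinb_oracle <- function(y, mu, theta, pi) {
  base <- dnbinom(y, mu = mu, size = theta)
  ifelse(y == 0, pi + (1 - pi) * base, (1 - pi) * base)
}

# Direct simulation of weekly records from the ZINB mixed process with a
# nested class x category design (no weather machinery) — the generating
# values are the oracle for recovery tests.
sim_zinb_records <- function(n, seed, rates, theta = 1.5, pi = 0.45,
                             sigma_u = 0.3, u = NULL,
                             groups = c("VS", "S", "M", "L", "VL"),
                             head_range = c(50, 2000)) {
  set.seed(seed)
  if (is.null(u)) u <- setNames(rnorm(length(groups), 0, sigma_u), groups)
  idx <- sample(nrow(rates), n, replace = TRUE)
  g <- sample(groups, n, replace = TRUE)
  N <- sample(head_range[1]:head_range[2], n, replace = TRUE)
  cr <- rates$cr[idx]
  mu <- N * cr / (1 - pi) * exp(u[g])
  y <- rzinb(n, mu = mu, theta = theta, pi = pi)
  list(
    data = tibble::tibble(
      condemned = pmin(y, N), total = N,
      class = rates$class[idx], category = rates$category[idx],
      volume_category = g),
    u = u
  )
}

# Frozen published risk ratios (two decimals) and attributable risks that
# the CR tables must reproduce definitionally.
published_rr <- function() {
  tibble::tribble(
    ~class,     ~axis,      ~category,   ~rr,
    "roaster",  "hi",       "moderate",  1.41,
    "roaster",  "hi",       "hot",       0.80,
    "roaster",  "hi",       "very_hot",  0.12,
    "market",   "hi",       "moderate",  1.27,
    "market",   "hi",       "hot",       1.37,
    "market",   "hi",       "very_hot",  1.17,
    "cull_sow", "hi",       "moderate",  2.07,
    "cull_sow", "hi",       "hot",       1.93,
    "cull_sow", "hi",       "very_hot",  2.26,
    "roaster",  "min_temp", "cool",      1.21,
    "roaster",  "min_temp", "cold",      1.55,
    "roaster",  "min_temp", "very_cold", 2.20,
    "market",   "min_temp", "cool",      0.97,
    "market",   "min_temp", "cold",      1.10,
    "market",   "min_temp", "very_cold", 1.43,
    "cull_sow", "min_temp", "cool",      0.81,
    "cull_sow", "min_temp", "cold",      0.85,
    "cull_sow", "min_temp", "very_cold", 1.07
  )
}

published_ar <- function() {
  tibble::tribble(
    ~class,     ~axis,      ~category,   ~ar,
    "roaster",  "hi",       "moderate",   0.0005,
    "roaster",  "hi",       "hot",       -0.00025,
    "roaster",  "hi",       "very_hot",  -0.00108,
    "market",   "hi",       "moderate",   0.0008,
    "market",   "hi",       "hot",        0.0011,
    "market",   "hi",       "very_hot",   0.0005,
    "cull_sow", "hi",       "moderate",   0.0029,
    "cull_sow", "hi",       "hot",        0.0025,
    "cull_sow", "hi",       "very_hot",   0.0034,
    "roaster",  "min_temp", "cool",       0.00026,
    "roaster",  "min_temp", "cold",       0.00068,
    "roaster",  "min_temp", "very_cold",  0.00148,
    "market",   "min_temp", "cool",      -0.0001,
    "market",   "min_temp", "cold",       0.0003,
    "market",   "min_temp", "very_cold",  0.0013,
    "cull_sow", "min_temp", "cool",      -0.0005,
    "cull_sow", "min_temp", "cold",      -0.0004,
    "cull_sow", "min_temp", "very_cold",  0.0002
  )
}

# Small direct simulation: baseline weeks plus labelled "extreme" weeks with
# a known multiplier on the per-head rate.
sim_revenue_data <- function(n_base, n_ext, seed, multiplier = 1,
                             pi = 0.3, theta = 3, sigma_u = 0.2) {
  set.seed(seed)
  u <- setNames(rnorm(5, 0, sigma_u), c("VS", "S", "M", "L", "VL"))
  mk <- function(n, axis, category, mult) {
    g <- sample(names(u), n, replace = TRUE)
    cls <- sample(c("market", "cull_sow", "roaster"), n, replace = TRUE)
    N <- sample(500:10000, n, replace = TRUE)
    cr <- c(market = 0.0030, cull_sow = 0.0027, roaster = 0.00123)[cls]
    y <- rzinb(n, mu = N * cr * mult / (1 - pi) * exp(u[g]), theta = theta,
               pi = pi)
    tibble::tibble(plant_id = "P1", week = sample(
      c("2013-W03", "2013-W28", "2014-W30"), n, replace = TRUE),
      class = cls, total = N, condemned = pmin(y, N),
      volume_category = g, axis = axis, category = category)
  }
  list(base = mk(n_base, "baseline", "baseline", 1),
       ext = mk(n_ext, "hi", "hot", multiplier), u = u)
}

# rates table (class, category, cr) on one axis plus the shared baseline
axis_rates <- function(axis) {
  cr <- cr_reference()
  cr[cr$axis %in% c("baseline", axis), c("class", "category", "cr")]
}
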