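# Synthetic surveillance-data generator with known ground truth.
#
# Emulates the four input streams (weekly slaughter records, station
# catalog, daily station weather, monthly price series) with the stated
# statistical structure: ZINB counts with a log-head offset, class-specific
# temperature effects, volume-category heterogeneity (a shared random
# intercept), seasonal sinusoidal weather driven by latitude, and seasonal
# prices with a summer peak for market hogs. Weekly condemnation counts are
# drawn from the zero-inflated NB process whose exposure category is
# computed by the *real* geoweather and heat-exposure modules on the
# generated weather, so category-assignment bugs surface in recovery tests.

#' Generator configuration
#'
#' Defaults are the study conditions: 150 plants over 6 years (2010-2015
#' calendar span), a volume-category mix matching the published share of
#' plant-weeks per category, published per-head condemnation rates as the
#' generating truth, dispersion `theta = 1.5`, structural-zero probability
#' `pi = 0.45` (roughly half of plant-weeks record no condemnations), and
#' random-intercept SD `sigma_u = 0.3`.
#'
#' @param seed integer RNG seed; the bundle is a deterministic function of
#'   the config.
#' @param n_plants,years,start_year study dimensions.
#' @param volume_mix named proportions over VS/S/M/L/VL plants.
#' @param true_cr tibble (`class`, `category`, `cr`) of generating per-head
#'   rates; default [cr_reference()].
#' @param theta,pi,sigma_u count-process parameters.
#' @param orphan_fraction fraction of plants whose stations all sit beyond
#'   100 miles (exercises the exclusion path).
#' @param daily_sd daily weather noise SD, degrees F.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 20100101, n_plants = 150, years = 6,
                             start_year = 2010,
                             volume_mix = c(VS = 0.219, S = 0.376, M = 0.103,
                                            L = 0.098, VL = 0.204),
                             true_cr = NULL, theta = 1.5, pi = 0.45,
                             sigma_u = 0.3, orphan_fraction = 0.02,
                             daily_sd = 4) {
  if (n_plants < 1) abort_domain("need at least one plant")
  if (years < 1) abort_domain("need at least one year")
  volume_mix <- volume_mix / sum(volume_mix)
  if (is.null(true_cr)) {
    true_cr <- cr_reference()[, c("class", "category", "cr")]
  }
  if (any(true_cr$cr <= 0 | true_cr$cr >= 1))
    abort_domain("generating rates must lie in (0, 1)")
  if (theta <= 0 || pi < 0 || pi >= 1 || sigma_u < 0)
    abort_domain("theta > 0, pi in [0, 1), sigma_u >= 0 required")
  structure(list(
    seed = as.integer(seed), n_plants = as.integer(n_plants),
    years = as.integer(years), start_year = as.integer(start_year),
    volume_mix = volume_mix, true_cr = true_cr, theta = theta, pi = pi,
    sigma_u = sigma_u, orphan_fraction = orphan_fraction,
    daily_sd = daily_sd,
    # class share of weekly head by volume category: the largest plants are
    # market-only; roasters come almost entirely from the smallest plants
    class_shares = list(
      VS = c(roaster = 0.45, market = 0.30, cull_sow = 0.25),
      S  = c(roaster = 0.20, market = 0.55, cull_sow = 0.25),
      M  = c(roaster = 0.00, market = 0.70, cull_sow = 0.30),
      L  = c(roaster = 0.00, market = 0.85, cull_sow = 0.15),
      VL = c(roaster = 0.00, market = 1.00, cull_sow = 0.00)
    )
  ), class = "generator_config")
}

# seasonal mean daily temperature for a latitude and day of year; annual
# mean and amplitude follow a rough US latitude gradient, peak around
# mid-July (day 199)
seasonal_temp <- function(lat, doy) {
  mean_t <- 72 - 1.8 * (lat - 30)
  amp <- 16 + 0.5 * (lat - 30)
  mean_t + amp * cos(2 * pi * (doy - 199) / 365.25)
}

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic surveillance bundle
#'
#' @param config a [generator_config()].
#' @return a `synthetic_bundle` list: `plants`, `stations`, `daily_weather`,
#'   `slaughter` (weekly records), `prices`, `truth` (every generating
#'   parameter, for recovery comparisons), `config`.
#' @export
generate <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_preserved_seed(config$seed, generate_impl(config))
}

generate_impl <- function(config) {
  np <- config$n_plants
  # --- plants -------------------------------------------------------------
  vol_cat <- sample(VOLUME_CATEGORIES, np, replace = TRUE,
                    prob = config$volume_mix)
  # ensure every volume category is represented when there is room
  if (np >= 5) {
    missing <- setdiff(VOLUME_CATEGORIES, unique(vol_cat))
    if (length(missing) > 0) vol_cat[seq_along(missing)] <- missing
  }
  base_head <- vapply(vol_cat, function(vc) {
    b <- VOLUME_BOUNDS[[vc]]
    if (vc == "VL") min(exp(rnorm(1, log(40000), 0.5)) + 15000, 150000)
    else runif(1, b[1], b[2])
  }, numeric(1))
  plants <- tibble(
    plant_id = sprintf("P%03d", seq_len(np)),
    lat = runif(np, 30, 47), lon = runif(np, -95, -75),
    volume_category = vol_cat, base_head = base_head
  )
  orphan <- runif(np) < config$orphan_fraction
  plants$orphan <- orphan
  # orphan plants sit on a remote grid, far from every other plant's
  # stations, so their only stations are the distant ones below and the
  # weather-linkage exclusion path is exercised deterministically
  if (any(orphan)) {
    k <- seq_len(sum(orphan)) - 1L
    plants$lat[orphan] <- 5 - 10 * (k %/% 25)
    plants$lon[orphan] <- -160 + 12 * (k %% 25)
  }

  # --- stations: 1-4 jittered 5-90 mi around each plant (orphans 150-400) --
  st_rows <- lapply(seq_len(np), function(i) {
    n_st <- sample(1:4, 1)
    d <- if (orphan[i]) runif(n_st, 150, 400) else runif(n_st, 5, 90)
    b <- runif(n_st, 0, 2 * pi)
    tibble(
      station_id = sprintf("W%03d%d", i, seq_len(n_st)),
      lat = pmin(89, pmax(-89, plants$lat[i] + d * cos(b) / 69.094)),
      lon = pmin(179.9, pmax(-179.9, plants$lon[i] +
                               d * sin(b) /
                               (69.094 * cos(plants$lat[i] * pi / 180))))
    )
  })
  stations <- bind_rows(st_rows)

  # --- daily station weather ----------------------------------------------
  dates <- seq(as.Date(paste0(config$start_year, "-01-01")),
               as.Date(paste0(config$start_year + config$years - 1, "-12-31")),
               by = "day")
  doy <- as.integer(format(dates, "%j"))
  nd <- length(dates)
  st_off <- rnorm(nrow(stations), 0, 1.5)   # per-station climate offset
  wx <- lapply(seq_len(nrow(stations)), function(s) {
    t_avg <- seasonal_temp(stations$lat[s], doy) + st_off[s] +
      rnorm(nd, 0, config$daily_sd)
    spread <- pmax(2, rnorm(nd, 13, 2))
    rh <- pmin(100, pmax(15, 75 - 0.40 * (t_avg - 60) + rnorm(nd, 0, 8)))
    tibble(station_id = stations$station_id[s], date = dates,
           t_avg = t_avg, t_min = t_avg - spread, rh = rh)
  })
  daily_weather <- bind_rows(wx)

  # --- weekly exposure via the real linkage + exposure modules -------------
  pww <- plant_week_weather(plants, stations, daily_weather)
  expo <- assign_exposure(pww$t_avg_week, pww$t_min_week, pww$rh_week)
  pww$axis <- expo$axis
  pww$category <- expo$category

  # --- weekly slaughter records -------------------------------------------
  weeks <- sort(unique(iso_week(dates)))
  u <- setNames(rnorm(5, 0, config$sigma_u), VOLUME_CATEGORIES)
  cr_lookup <- setNames(config$true_cr$cr,
                        paste(config$true_cr$class, config$true_cr$category))
  grid <- tidyr::expand_grid(plant_id = plants$plant_id, week = weeks)
  grid <- left_join(grid, plants[, c("plant_id", "volume_category",
                                     "base_head")], by = "plant_id")
  grid <- left_join(grid, pww[, c("plant_id", "week", "category")],
                    by = c("plant_id", "week"))
  n_pw <- nrow(grid)
  grid$head <- pmax(30, round(grid$base_head * exp(rnorm(n_pw, 0, 0.08))))

  share_mat <- do.call(rbind, config$class_shares)
  rec <- lapply(SWINE_CLASSES, function(cl) {
    share <- share_mat[grid$volume_category, cl]
    # per-plant jitter in class composition
    jit <- exp(rnorm(n_pw, 0, 0.15))
    n_cl <- round(grid$head * share * jit)
    keep <- n_cl >= 1
    if (!any(keep)) return(NULL)
    cat_cl <- grid$category[keep]
    cat_cl[is.na(cat_cl)] <- "baseline"   # unlinked/excluded weeks still occur
    cr <- cr_lookup[paste(cl, cat_cl)]
    cr[is.na(cr)] <- cr_lookup[paste(cl, "baseline")]
    mu <- n_cl[keep] * cr / (1 - config$pi) *
      exp(u[grid$volume_category[keep]])
    cond <- rzinb(sum(keep), mu = mu, theta = config$theta, pi = config$pi)
    tibble(plant_id = grid$plant_id[keep], week = grid$week[keep],
           class = cl, total = n_cl[keep],
           condemned = pmin(cond, n_cl[keep]),
           volume_category = grid$volume_category[keep])
  })
  slaughter <- bind_rows(rec) %>% arrange(.data$plant_id, .data$week,
                                          .data$class)

  # --- monthly price series (summer peak for market; distinct shape for
  #     cull sows, peaking in early autumn) --------------------------------
  # one month of padding each side: edge ISO weeks can have their majority
  # month in the adjacent calendar year
  pm <- tidyr::expand_grid(year = config$start_year +
                             seq_len(config$years) - 1L, month = 1:12)
  pm <- bind_rows(
    tibble(year = config$start_year - 1L, month = 12L),
    pm,
    tibble(year = config$start_year + config$years, month = 1L)
  )
  m <- pm$month
  prices <- bind_rows(
    tibble(year = pm$year, month = m, class = "market",
           price_per_head = 140 + 22 * cos(2 * pi * (m - 7) / 12) +
             rnorm(nrow(pm), 0, 4),
           dressed_price_per_cwt = 74 + 11 * cos(2 * pi * (m - 7) / 12) +
             rnorm(nrow(pm), 0, 2)),
    tibble(year = pm$year, month = m, class = "cull_sow",
           price_per_head = 68 + 10 * cos(2 * pi * (m - 9.5) / 12) +
             rnorm(nrow(pm), 0, 3),
           dressed_price_per_cwt = NA_real_)
  )

  truth <- list(
    seed = config$seed, n_plants = config$n_plants, years = config$years,
    start_year = config$start_year, volume_mix = config$volume_mix,
    true_cr = config$true_cr, theta = config$theta, pi = config$pi,
    sigma_u = config$sigma_u, u = u,
    class_shares = config$class_shares,
    orphan_plants = plants$plant_id[orphan],
    orphan_head = sum(slaughter$total[slaughter$plant_id %in%
                                        plants$plant_id[orphan]])
  )
  structure(list(plants = plants[, c("plant_id", "lat", "lon",
                                     "volume_category", "orphan")],
                 stations = stations, daily_weather = daily_weather,
                 slaughter = slaughter, prices = prices, truth = truth,
                 config = config),
            class = "synthetic_bundle")
}

#' Ground-truth record of a synthetic bundle
#'
#' @param bundle a `synthetic_bundle`.
#' @return the list of every generating parameter (seed, rates, dispersion,
#'   zero inflation, random-intercept draws, orphan plants, ...).
#' @export
truth_report <- function(bundle) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  bundle$truth
}

#' Write a bundle as the CSV fixture set the pipeline reads
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$plants, file.path(dir, "plants.csv"), row.names = FALSE)
  write.csv(bundle$stations, file.path(dir, "stations.csv"),
            row.names = FALSE)
  write.csv(bundle$daily_weather, file.path(dir, "daily_weather.csv"),
            row.names = FALSE)
  write.csv(bundle$slaughter, file.path(dir, "slaughter.csv"),
            row.names = FALSE)
  write.csv(bundle$prices, file.path(dir, "prices.csv"), row.names = FALSE)
  invisible(dir)
}
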