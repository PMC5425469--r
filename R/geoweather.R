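# Plant-to-station linkage and weekly weather aggregation.
#
# Each slaughter plant is matched to its closest 1-3 weather stations within
# 100 statute miles by great-circle distance; daily station observations are
# then pooled (unweighted) into plant-week summaries. Plants with no station
# inside the radius are excluded downstream with a logged count.

# Fixed Earth radius so distances are bit-reproducible.
EARTH_RADIUS_MILES <- 3958.8

#' Great-circle distance in statute miles
#'
#' Haversine distance on a sphere of fixed radius 3,958.8 statute miles.
#' Vectorised over all four coordinate arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @param radius Earth radius in miles (default `EARTH_RADIUS_MILES`).
#' @return non-negative distances in statute miles.
#' @examples
#' haversine_miles(0, 0, 1, 0)   # one degree of meridian, ~69.09 mi
#' @export
haversine_miles <- function(lat1, lon1, lat2, lon2,
                            radius = EARTH_RADIUS_MILES) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  p <- pi / 180
  dlat <- (lat2 - lat1) * p
  dlon <- (lon2 - lon1) * p
  a <- sin(dlat / 2)^2 + cos(lat1 * p) * cos(lat2 * p) * sin(dlon / 2)^2
  a <- pmin(1, a)
  2 * radius * asin(sqrt(a))
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    abort_domain("latitude must lie in [-90, 90] and longitude in [-180, 180]")
  invisible(TRUE)
}

#' Assign the closest weather stations to a plant
#'
#' Returns up to `k` stations within `max_miles` of the plant, ordered by
#' ascending distance. An empty result is valid: such plants are excluded
#' from modelling downstream (mirroring the loss of records that have no
#' usable weather linkage).
#'
#' @param plant a one-row data frame (or list) with `lat` and `lon`.
#' @param stations data frame with `station_id`, `lat`, `lon`.
#' @param max_miles search radius (default 100).
#' @param k maximum number of stations (default 3).
#' @return tibble with `station_id` and `distance_miles`, sorted ascending.
#' @export
assign_stations <- function(plant, stations, max_miles = 100, k = 3) {
  if (nrow(stations) == 0) abort_domain("station catalog is empty")
  d <- haversine_miles(plant$lat, plant$lon, stations$lat, stations$lon)
  keep <- which(d <= max_miles)
  keep <- keep[order(d[keep])]
  if (length(keep) > k) keep <- keep[seq_len(k)]
  tibble(station_id = stations$station_id[keep], distance_miles = d[keep])
}

#' Weekly weather summary for one plant
#'
#' Unweighted mean of daily observations across the assigned stations and the
#' days of one ISO week. `t_min_week` is the weekly mean of daily minima.
#'
#' @param daily data frame of daily observations (`station_id`, `date`,
#'   `t_avg`, `t_min`, `rh`).
#' @param station_ids stations assigned to the plant.
#' @param week ISO week label `"YYYY-Www"`.
#' @return one-row tibble (`week`, `t_avg_week`, `t_min_week`, `rh_week`,
#'   `n_stations_used`, `n_days`), or a zero-row tibble when the week has no
#'   observations (the missing-week marker; such plant-weeks are excluded
#'   from modelling).
#' @export
weekly_weather <- function(daily, station_ids, week) {
  d <- daily[daily$station_id %in% station_ids &
               iso_week(daily$date) == week, , drop = FALSE]
  d <- d[stats::complete.cases(d[, c("t_avg", "t_min", "rh")]), , drop = FALSE]
  if (nrow(d) == 0)
    return(tibble(week = character(), t_avg_week = numeric(),
                  t_min_week = numeric(), rh_week = numeric(),
                  n_stations_used = integer(), n_days = integer()))
  tibble(
    week = week,
    t_avg_week = mean(d$t_avg),
    t_min_week = mean(d$t_min),
    rh_week = mean(d$rh),
    n_stations_used = length(unique(d$station_id)),
    n_days = length(unique(d$date))
  )
}

#' Plant-week weather table for all plants
#'
#' Runs station assignment and weekly aggregation over a whole plant catalog.
#' Partial weeks (at least `min_days` distinct days reported) are kept.
#'
#' @param plants data frame with `plant_id`, `lat`, `lon`.
#' @param stations data frame with `station_id`, `lat`, `lon`.
#' @param daily data frame of daily station observations.
#' @param max_miles,k station search radius and count (defaults 100 mi, 3).
#' @param min_days minimum distinct days required to keep a plant-week
#'   (default 1; set 4 to require most of the week).
#' @return tibble keyed by (`plant_id`, `week`) with weekly means and
#'   `n_stations_used`; plants with no qualifying station are absent and
#'   listed in `attr(, "excluded_plants")`.
#' @export
plant_week_weather <- function(plants, stations, daily, max_miles = 100,
                               k = 3, min_days = 1) {
  assign_one <- function(i) {
    a <- assign_stations(plants[i, ], stations, max_miles, k)
    if (nrow(a) == 0) return(NULL)
    tibble(plant_id = plants$plant_id[i], station_id = a$station_id)
  }
  links <- bind_rows(lapply(seq_len(nrow(plants)), assign_one))
  excluded <- setdiff(plants$plant_id, links$plant_id)
  if (nrow(links) == 0)
    abort_domain("no plant has a weather station within ", max_miles, " miles")
  d <- daily[stats::complete.cases(daily[, c("t_avg", "t_min", "rh")]), ,
             drop = FALSE]
  d <- left_join(links, d, by = "station_id", relationship = "many-to-many")
  d <- d[!is.na(d$date), , drop = FALSE]
  d$week <- iso_week(d$date)
  out <- d %>%
    group_by(.data$plant_id, .data$week) %>%
    summarise(
      t_avg_week = mean(.data$t_avg),
      t_min_week = mean(.data$t_min),
      rh_week = mean(.data$rh),
      n_stations_used = length(unique(.data$station_id)),
      n_days = length(unique(.data$date)),
      .groups = "drop"
    ) %>%
    filter(.data$n_days >= min_days)
  attr(out, "excluded_plants") <- excluded
  out
}
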