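# Heat-index computation and exposure categorization.
#
# The heat index (apparent temperature, degrees F) is the NWS Rothfusz
# regression, defined for ambient temperatures of 80 F and above, with the
# two standard NWS adjustments (low-humidity subtraction, high-humidity
# addition). Weekly exposure is categorized on one of two axes: heat index
# (moderate / hot / very_hot) for warm weeks, or weekly-mean minimum
# temperature (cool / cold / very_cold) for cold weeks, with a baseline of
# mild weeks (minimum above 50 F, average 54-79 F). Category bounds are
# compared on degrees F rounded to the nearest integer, matching the
# integer-labelled bins the scheme was calibrated on.

#' Exposure category bounds
#'
#' The fixed category bound table (degrees F, inclusive, compared on
#' integer-rounded values) used throughout the pipeline. Exported for
#' inspection and sensitivity analysis; the published calibration is the
#' default everywhere.
#'
#' @format tibble with `axis`, `category`, `lo`, `hi`.
#' @export
EXPOSURE_BOUNDS <- tibble::tribble(
  ~axis,      ~category,   ~lo,  ~hi,
  "hi",       "moderate",   80,   84,
  "hi",       "hot",        85,   92,
  "hi",       "very_hot",   93,  106,
  "min_temp", "cool",       40,   50,
  "min_temp", "cold",       10,   39,
  "min_temp", "very_cold", -17,    9,
  "baseline", "baseline",   54,   79
)

#' Heat index (apparent temperature)
#'
#' Rothfusz nine-coefficient regression in temperature and relative humidity,
#' plus the two standard NWS adjustments: for `rh < 13` and `80 <= t <= 112`
#' a low-humidity subtraction, and for `rh > 85` and `80 <= t <= 87` a
#' high-humidity addition. The index is defined only for `t >= 80`; below
#' that the result is `NA` (not a valid apparent temperature).
#'
#' @param t ambient temperature, degrees F.
#' @param rh relative humidity, percent in \[0, 100\].
#' @return heat index in degrees F; `NA_real_` where `t < 80`.
#' @examples
#' heat_index(90, 50)  # 94.60
#' @export
heat_index <- function(t, rh) {
  if (any(!is.finite(rh)) || any(rh < 0 | rh > 100))
    abort_domain("relative humidity must lie in [0, 100]")
  n <- max(length(t), length(rh))
  t <- rep_len(t, n)
  rh <- rep_len(rh, n)
  hi <- -42.379 + 2.04901523 * t + 10.14333127 * rh -
    0.22475541 * t * rh - 6.83783e-3 * t^2 - 5.481717e-2 * rh^2 +
    1.22874e-3 * t^2 * rh + 8.5282e-4 * t * rh^2 - 1.99e-6 * t^2 * rh^2
  low <- rh < 13 & t >= 80 & t <= 112
  hi[low] <- hi[low] -
    ((13 - rh[low]) / 4) * sqrt((17 - abs(t[low] - 95)) / 17)
  high <- rh > 85 & t >= 80 & t <= 87
  hi[high] <- hi[high] + ((rh[high] - 85) / 10) * ((87 - t[high]) / 5)
  hi[t < 80] <- NA_real_
  hi
}

#' Heat-index exposure category
#'
#' Bins a valid heat-index value (rounded to integer degrees F) into
#' `moderate` \[80, 84\], `hot` \[85, 92\], or `very_hot` \[93, 106\].
#' Values above 106 are outside the calibration range of the category scheme
#' and raise an error; so do invalid (`NA`, below-80) inputs.
#'
#' @param hi heat-index values in degrees F.
#' @return character vector of category labels.
#' @export
categorize_hi <- function(hi) {
  if (any(is.na(hi))) abort_domain("heat index is only defined for t >= 80")
  h <- round(hi)
  if (any(h > 106))
    abort_domain("heat index above 106 F is outside the calibration range")
  if (any(h < 80))
    abort_domain("heat index below 80 F cannot be categorized")
  c("moderate", "hot", "very_hot")[findInterval(h, c(80, 85, 93))]
}

#' Minimum-temperature exposure category
#'
#' Weeks with rounded weekly-mean minimum temperature of 50 F or below are
#' binned into `cool` \[40, 50\], `cold` \[10, 39\], or `very_cold`
#' \[-17, 9\]. Warmer weeks are `baseline` when the weekly average is
#' 54-79 F, or `"hi_axis"` (routed to the heat-index axis) when the weekly
#' average reaches 80 F. Rounded minima below -17 F are outside the
#' calibration range.
#'
#' @param t_min_week weekly mean of daily minimum temperatures, degrees F.
#' @param t_avg_week weekly mean temperature, degrees F.
#' @return character vector: `very_cold`, `cold`, `cool`, `baseline`,
#'   `hi_axis`, or `NA` for the mild gap not covered by any bin.
#' @export
categorize_min_temp <- function(t_min_week, t_avg_week) {
  if (any(!is.finite(t_min_week)) || any(!is.finite(t_avg_week)))
    abort_domain("temperatures must be finite")
  tm <- round(t_min_week)
  ta <- round(t_avg_week)
  if (any(tm < -17))
    abort_domain("minimum temperature below -17 F is outside the calibration range")
  out <- rep(NA_character_, length(tm))
  out[tm <= 50 & tm >= 40] <- "cool"
  out[tm <= 39 & tm >= 10] <- "cold"
  out[tm <= 9] <- "very_cold"
  warm <- tm > 50
  out[warm & t_avg_week >= 80] <- "hi_axis"
  out[warm & t_avg_week < 80 & ta >= 54 & ta <= 79] <- "baseline"
  out
}

#' Exhaustive exposure assignment for plant-weeks
#'
#' Maps every plant-week to exactly one of the seven exposure categories or
#' excludes it with a reason, so the modelled set is an exact partition:
#' * cold axis when the rounded weekly minimum is 50 F or below (takes
#'   priority over the heat-index axis);
#' * heat-index axis when the weekly average reaches 80 F (the index's
#'   validity domain) and the minimum exceeds 50 F;
#' * baseline when the minimum exceeds 50 F and the rounded average is
#'   54-79 F.
#' Excluded reasons: `hi_below_80` (index falls under 80 at low humidity),
#' `hi_above_calibration` (index above 106), `min_below_calibration`
#' (minimum below -17), `temperature_gap` (average 51-53 with warm minimum).
#'
#' @param t_avg_week,t_min_week,rh_week weekly weather summaries.
#' @return tibble with `axis` (`hi`, `min_temp`, `baseline`, or `excluded`),
#'   `category` (label or `NA` when excluded), `hi` (heat index or `NA`),
#'   and `reason` (`NA` unless excluded).
#' @export
assign_exposure <- function(t_avg_week, t_min_week, rh_week) {
  n <- length(t_avg_week)
  stopifnot(length(t_min_week) == n, length(rh_week) == n)
  axis <- rep("excluded", n)
  category <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  hi <- rep(NA_real_, n)

  tm <- round(t_min_week)
  ta <- round(t_avg_week)

  cold <- tm <= 50
  toocold <- cold & tm < -17
  axis[cold & !toocold] <- "min_temp"
  category[cold & !toocold] <-
    c("very_cold", "cold", "cool")[findInterval(tm[cold & !toocold],
                                                c(-17, 10, 40))]
  axis[toocold] <- "excluded"
  reason[toocold] <- "min_below_calibration"

  warm <- !cold & t_avg_week >= 80
  hi[warm] <- heat_index(t_avg_week[warm], rh_week[warm])
  hir <- round(hi)
  ok <- warm & hir >= 80 & hir <= 106
  axis[ok] <- "hi"
  category[ok] <- c("moderate", "hot", "very_hot")[findInterval(hir[ok],
                                                                c(80, 85, 93))]
  reason[warm & hir < 80] <- "hi_below_80"
  reason[warm & hir > 106] <- "hi_above_calibration"

  base <- !cold & !warm & ta >= 54 & ta <= 79
  axis[base] <- "baseline"
  category[base] <- "baseline"
  reason[!cold & !warm & !base] <- "temperature_gap"

  tibble(axis = axis, category = category, hi = hi, reason = reason)
}

#' Offset-weighted cubic smoothing spline of the condemnation rate
#'
#' Smooths the per-head condemnation rate `y / total` against a temperature
#' predictor with observations weighted by head count, so high-volume plants
#' are proportionally more influential (the offset-as-weight reading of a
#' log-total offset in rate smoothing). The smoothing parameter is chosen by
#' generalized cross-validation unless supplied.
#'
#' @param x predictor (degrees F), one value per plant-week.
#' @param y condemned head counts.
#' @param total head slaughtered (>= 1).
#' @param smoothing optional fixed `spar` for [stats::smooth.spline()].
#' @param grid_length grid resolution for fitted intensities (default 201).
#' @return an `offset_spline` object: `grid`, `intensity` (fitted per-head
#'   rate, clamped at zero), `spar`, and the underlying smooth.
#' @export
fit_offset_spline <- function(x, y, total, smoothing = NULL,
                              grid_length = 201) {
  if (any(total < 1)) abort_domain("total head must be >= 1 for every record")
  if (length(unique(x)) < 10)
    abort_domain("need at least 10 distinct predictor values")
  rate <- y / total
  ss <- if (is.null(smoothing)) {
    smooth.spline(x, rate, w = total, cv = FALSE)
  } else {
    smooth.spline(x, rate, w = total, spar = smoothing)
  }
  # evaluation grid spans the central mass of the predictor; the extreme
  # tails are too sparse to support a stable rate estimate
  qs <- quantile(x, c(0.01, 0.99), names = FALSE)
  grid <- seq(qs[1], qs[2], length.out = grid_length)
  intensity <- pmax(0, predict(ss, grid)$y)
  structure(list(grid = grid, intensity = intensity, spar = ss$spar,
                 smooth = ss, offset_used = TRUE),
            class = "offset_spline")
}

#' Suggest category breakpoints from a fitted rate spline
#'
#' Advisory cutpoints at the `k` largest-curvature positions of the fitted
#' curve (local maxima of the absolute second derivative). When the curve is
#' essentially flat the fallback is predictor quantiles. Pipeline defaults
#' always use the fixed published category bounds; this explorer only
#' justifies them.
#'
#' @param fit an `offset_spline` object.
#' @param k number of cutpoints (>= 1).
#' @return numeric vector of `k` cutpoints in degrees F, sorted.
#' @export
suggest_breakpoints <- function(fit, k) {
  stopifnot(inherits(fit, "offset_spline"))
  if (k < 1) abort_domain("k must be at least 1")
  grid <- fit$grid
  if (k >= length(grid)) abort_domain("k exceeds the grid support")
  curv <- abs(predict(fit$smooth, grid, deriv = 2)$y)
  flat <- diff(range(fit$intensity)) <=
    1e-8 * (abs(mean(fit$intensity)) + .Machine$double.eps)
  if (flat) {
    return(unname(quantile(grid, probs = seq_len(k) / (k + 1))))
  }
  # local maxima of curvature, strongest first
  n <- length(curv)
  is_peak <- c(FALSE, curv[2:(n - 1)] >= curv[1:(n - 2)] &
                 curv[2:(n - 1)] >= curv[3:n], FALSE)
  peaks <- which(is_peak)
  peaks <- peaks[order(curv[peaks], decreasing = TRUE)]
  if (length(peaks) < k) {
    extra <- setdiff(order(curv, decreasing = TRUE), peaks)
    peaks <- c(peaks, extra)[seq_len(k)]
  } else {
    peaks <- peaks[seq_len(k)]
  }
  sort(grid[peaks])
}
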