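# Counterfactual foregone-revenue attribution.
#
# A baseline-weeks model (class-only fixed effects, log-head offset,
# volume-category random intercept) predicts the "dead" condemnations each
# extreme-temperature week would have seen absent the temperature signal.
# The signed residual observed - expected is attributed to temperature,
# summed per category, and priced with the monthly carcass price series.

#' Fit the baseline-weeks counterfactual model
#'
#' ZINB mixed model on baseline plant-weeks only (minimum above 50 F,
#' average 54-79 F), with swine class as the only fixed effect. It predicts
#' condemnations due to causes other than temperature.
#'
#' @param data weekly records carrying an `axis` column; only
#'   `axis == "baseline"` rows are used.
#' @param ... passed to [fit_zinb_glmm()].
#' @return a `zinb_fit`.
#' @export
fit_baseline_model <- function(data, ...) {
  base <- data[data$axis == "baseline", , drop = FALSE]
  missing <- setdiff(unique(data$class), unique(base$class))
  if (length(missing) > 0)
    abort_domain("no baseline weeks for class(es): ",
                 paste(missing, collapse = ", "))
  if (nrow(base) == 0) abort_domain("no baseline weeks in the data")
  fit_zinb_glmm(base, category_col = NULL, ...)
}

#' Excess condemnations on extreme-temperature weeks
#'
#' Expected counts use the baseline model with the record's estimated
#' volume-category random-effect mode (`prediction = "conditional"`, the
#' default), i.e. the counterfactual for the same plants; excess is the
#' signed residual observed - expected (negative allowed — categories can
#' sit below their counterfactual).
#'
#' @param fit_baseline a converged `zinb_fit` from [fit_baseline_model()].
#' @param extreme_weeks records with `axis` in `hi` / `min_temp`, exposure
#'   `category`, `class`, `condemned`, `total`, `volume_category`, `week`,
#'   `plant_id`.
#' @param prediction `"conditional"` (include the group mode) or
#'   `"population"`.
#' @return ledger tibble: row-level `observed`, `expected`, `excess` keyed
#'   by (`plant_id`, `week`, `class`, `axis`, `category`), with `total` and
#'   the week's majority month.
#' @export
excess_condemnations <- function(fit_baseline, extreme_weeks,
                                 prediction = c("conditional", "population")) {
  prediction <- match.arg(prediction)
  if (!fit_baseline$converged) abort_domain("baseline fit did not converge")
  if (any(is.na(extreme_weeks$volume_category)))
    abort_domain("extreme weeks lack a volume category")
  expected <- predict(fit_baseline, extreme_weeks, prediction = prediction)
  ym <- iso_week_month(extreme_weeks$week)
  tibble(
    plant_id = extreme_weeks$plant_id,
    week = extreme_weeks$week,
    year = ym$year, month = ym$month,
    class = extreme_weeks$class,
    axis = extreme_weeks$axis,
    category = extreme_weeks$category,
    total = extreme_weeks$total,
    observed = extreme_weeks$condemned,
    expected = expected,
    excess = extreme_weeks$condemned - expected
  )
}

#' Price excess condemnations with a monthly price series
#'
#' Market and cull-sow rows are priced at the class's monthly price per
#' head; roaster rows (absent from price reports) are priced from the
#' market dressed price as `(70 lbs median roaster carcass / 100) *
#' dressed_price_per_cwt`. Prices attach by the ISO week's majority month.
#'
#' @param ledger rows from [excess_condemnations()].
#' @param prices tibble with `year`, `month`, `class` (`market`,
#'   `cull_sow`), `price_per_head`, and (market rows) a
#'   `dressed_price_per_cwt` column.
#' @param roaster_carcass_lbs median roaster carcass weight (default 70).
#' @return the ledger with `price_per_head` and
#'   `foregone_usd = excess * price_per_head` columns.
#' @export
price_condemnations <- function(ledger, prices, roaster_carcass_lbs = 70) {
  if (any(prices$price_per_head <= 0, na.rm = TRUE))
    abort_domain("prices must be positive")
  market <- prices[prices$class == "market", , drop = FALSE]
  roaster_prices <- tibble(
    year = market$year, month = market$month, class = "roaster",
    price_per_head = roaster_carcass_lbs / 100 * market$dressed_price_per_cwt
  )
  lookup <- bind_rows(
    prices[, c("year", "month", "class", "price_per_head")],
    roaster_prices
  )
  out <- left_join(ledger, lookup, by = c("year", "month", "class"))
  if (any(is.na(out$price_per_head))) {
    miss <- unique(out[is.na(out$price_per_head),
                       c("year", "month", "class")])
    abort_domain("no price for: ",
                 paste(sprintf("%s %d-%02d", miss$class, miss$year,
                               miss$month), collapse = ", "))
  }
  out$foregone_usd <- out$excess * out$price_per_head
  out
}

#' Summarize the revenue ledger by class and exposure category
#'
#' Category sums of excess condemnations and foregone revenue, the head
#' slaughtered in the category, and the percent of those head condemned due
#' to extreme temperature, plus a `Total` row per class and axis. Row-level
#' excess sums are preserved exactly (ledger conservation).
#'
#' @param ledger priced rows from [price_condemnations()].
#' @return tibble: `class`, `axis`, `category` (including `"total"` rows),
#'   `increased`, `foregone_usd_k` (USD thousands), `head_k` (thousands),
#'   `percent`.
#' @export
summarize_ledger <- function(ledger) {
  per_cat <- ledger %>%
    group_by(.data$class, .data$axis, .data$category) %>%
    summarise(increased = sum(.data$excess),
              foregone_usd_k = sum(.data$foregone_usd) / 1000,
              head_k = sum(.data$total) / 1000,
              .groups = "drop")
  totals <- per_cat %>%
    group_by(.data$class, .data$axis) %>%
    summarise(category = "total",
              increased = sum(.data$increased),
              foregone_usd_k = sum(.data$foregone_usd_k),
              head_k = sum(.data$head_k),
              .groups = "drop")
  bind_rows(per_cat, totals) %>%
    mutate(percent = .data$increased / (.data$head_k * 1000) * 100) %>%
    arrange(.data$class, .data$axis, .data$category != "total")
}
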