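# End-to-end orchestration: weather linkage -> exposure -> two ZINB mixed
# model fits (heat-index axis, minimum-temperature axis, sharing the same
# baseline rows) -> risk tables -> counterfactual revenue attribution, with
# a manifest that accounts for every input record exactly once.

#' Validate pipeline input tables
#'
#' Schema, range, and duplicate-key checks. Violations are returned, not
#' raised, so a run can report them all at once.
#'
#' @param slaughter,stations,daily_weather,prices input tables (any may be
#'   `NULL` to skip its checks).
#' @return tibble of violations: `table`, `row`, `rule`.
#' @export
validate_inputs <- function(slaughter = NULL, stations = NULL,
                            daily_weather = NULL, prices = NULL) {
  v <- list()
  flag <- function(tbl, rows, rule) {
    if (length(rows) > 0)
      v[[length(v) + 1L]] <<- tibble(table = tbl, row = as.integer(rows),
                                     rule = rule)
  }
  if (!is.null(slaughter)) {
    flag("slaughter", which(slaughter$condemned > slaughter$total),
         "condemned > total")
    flag("slaughter", which(slaughter$condemned < 0), "condemned < 0")
    flag("slaughter", which(slaughter$total < 1), "total < 1")
    key <- paste(slaughter$plant_id, slaughter$week, slaughter$class)
    flag("slaughter", which(duplicated(key)), "duplicate (plant, week, class)")
    flag("slaughter", which(!slaughter$class %in% SWINE_CLASSES),
         "unknown swine class")
  }
  if (!is.null(stations)) {
    flag("stations", which(abs(stations$lat) > 90 | abs(stations$lon) > 180),
         "coordinates out of range")
    flag("stations", which(duplicated(stations$station_id)),
         "duplicate station_id")
  }
  if (!is.null(daily_weather)) {
    flag("daily_weather",
         which(daily_weather$rh < 0 | daily_weather$rh > 100),
         "rh outside [0, 100]")
    flag("daily_weather",
         which(daily_weather$t_min > daily_weather$t_avg), "t_min > t_avg")
  }
  if (!is.null(prices)) {
    flag("prices", which(prices$price_per_head <= 0), "non-positive price")
  }
  if (length(v) == 0)
    tibble(table = character(), row = integer(), rule = character())
  else bind_rows(v)
}

read_input_dir <- function(dir) {
  rd <- function(f, dates = NULL) {
    path <- file.path(dir, f)
    if (!file.exists(path)) abort_domain("missing input file: ", path)
    x <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
    if (!is.null(dates)) for (col in dates) x[[col]] <- as.Date(x[[col]])
    x
  }
  list(plants = rd("plants.csv"), stations = rd("stations.csv"),
       daily_weather = rd("daily_weather.csv", dates = "date"),
       slaughter = rd("slaughter.csv"), prices = rd("prices.csv"))
}

#' Run the full condemnation-weather pipeline
#'
#' Stages: weather linkage (closest 1-3 stations within 100 miles), weekly
#' exposure assignment, two nested-design ZINB mixed-model fits (heat-index
#' axis and minimum-temperature axis, each pooling the shared baseline
#' rows), risk tables, and counterfactual foregone-revenue attribution
#' against a baseline-weeks class-only model. Writes six table files, three
#' figure-data files (weekly DLR and foregone revenue per class), two fit
#' reports, and a JSON manifest.
#'
#' @param config list with either `input_dir` (a CSV fixture directory) or
#'   `synthetic` (arguments for [generator_config()]), plus `out_dir`,
#'   optional `seed` (overrides the synthetic seed), `quad_points`
#'   (default 15), `prediction` (`"conditional"`/`"population"`), and
#'   `min_days`. May also be a path to a YAML file with those keys.
#' @return the manifest list, invisibly; all outputs under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) abort_domain("config needs an out_dir")
  has_input <- !is.null(config$input_dir)
  has_synth <- !is.null(config$synthetic)
  if (has_input == has_synth)
    abort_domain("config needs exactly one of input_dir or synthetic")
  quad_points <- config$quad_points %||% 15
  prediction <- config$prediction %||% "conditional"
  min_days <- config$min_days %||% 1

  if (has_synth) {
    args <- config$synthetic
    if (isTRUE(args)) args <- list()
    if (!is.null(config$seed)) args$seed <- config$seed
    bundle <- generate(do.call(generator_config, args))
    inputs <- bundle[c("plants", "stations", "daily_weather", "slaughter",
                       "prices")]
    truth <- bundle$truth
  } else {
    inputs <- read_input_dir(config$input_dir)
    truth <- NULL
  }

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "INVALID"))
  stage <- "validate"
  manifest <- list(package_version = as.character(
    utils::packageVersion("swinecondemn")), seed = config$seed %||%
      (if (has_synth) bundle$config$seed else NA))
  result <- tryCatch({
    violations <- validate_inputs(inputs$slaughter, inputs$stations,
                                  inputs$daily_weather, inputs$prices)
    invalid_rows <- unique(violations$row[violations$table == "slaughter"])
    slaughter <- inputs$slaughter
    slaughter$row_id <- seq_len(nrow(slaughter))
    valid <- !slaughter$row_id %in% invalid_rows

    stage <- "geoweather"
    pww <- plant_week_weather(inputs$plants, inputs$stations,
                              inputs$daily_weather, min_days = min_days)

    stage <- "heat_exposure"
    expo <- assign_exposure(pww$t_avg_week, pww$t_min_week, pww$rh_week)
    pww <- bind_cols(pww, expo[, c("axis", "category", "hi", "reason")])
    write.csv(pww, file.path(out_dir, "plant_week_weather.csv"),
              row.names = FALSE)

    recs <- left_join(slaughter[valid, , drop = FALSE],
                      pww[, c("plant_id", "week", "axis", "category")],
                      by = c("plant_id", "week"))
    recs$status <- dplyr::case_when(
      is.na(recs$axis) ~ "excluded_no_weather",
      recs$axis == "excluded" ~ "excluded_out_of_range",
      recs$axis == "baseline" ~ "baseline",
      TRUE ~ "modelled"
    )
    modelled <- recs[recs$status %in% c("baseline", "modelled"), ,
                     drop = FALSE]

    stage <- "zinb_glmm"
    hi_data <- modelled[modelled$axis %in% c("baseline", "hi"), ,
                        drop = FALSE]
    cold_data <- modelled[modelled$axis %in% c("baseline", "min_temp"), ,
                          drop = FALSE]
    fit_hi <- fit_zinb_glmm(hi_data, category_col = "category",
                            quad_points = quad_points)
    fit_cold <- fit_zinb_glmm(cold_data, category_col = "category",
                              quad_points = quad_points)
    write_fit_report(fit_hi, file.path(out_dir, "fit_hi.json"),
                     file.path(out_dir, "fit_hi.txt"))
    write_fit_report(fit_cold, file.path(out_dir, "fit_cold.json"),
                     file.path(out_dir, "fit_cold.txt"))

    stage <- "risk_metrics"
    risk_hi <- build_risk_table(fit_hi)
    risk_cold <- build_risk_table(fit_cold)
    write.csv(risk_hi[, c("class", "category", "cr", "ar", "eir")],
              file.path(out_dir, "table_risk_hi.csv"), row.names = FALSE)
    write.csv(risk_hi[, c("class", "category", "rr", "rr_lo", "rr_hi")],
              file.path(out_dir, "table_rr_hi.csv"), row.names = FALSE)
    write.csv(risk_cold[, c("class", "category", "cr", "ar", "eir")],
              file.path(out_dir, "table_risk_cold.csv"), row.names = FALSE)
    write.csv(risk_cold[, c("class", "category", "rr", "rr_lo", "rr_hi")],
              file.path(out_dir, "table_rr_cold.csv"), row.names = FALSE)
    dlr_monthly <- dlr_table(recs)
    write.csv(dlr_monthly, file.path(out_dir, "table_dlr_monthly.csv"),
              row.names = FALSE)

    stage <- "revenue"
    fit_base <- fit_baseline_model(modelled, quad_points = quad_points)
    extreme <- modelled[modelled$axis %in% c("hi", "min_temp"), ,
                        drop = FALSE]
    ledger <- excess_condemnations(fit_base, extreme,
                                   prediction = prediction)
    ledger <- price_condemnations(ledger, inputs$prices)
    revenue_summary <- summarize_ledger(ledger)
    write.csv(revenue_summary, file.path(out_dir, "table_revenue.csv"),
              row.names = FALSE)
    write.csv(ledger, file.path(out_dir, "revenue_ledger.csv"),
              row.names = FALSE)

    # figure data: weekly DLR and foregone revenue per class
    for (cl in intersect(SWINE_CLASSES, unique(recs$class))) {
      weekly <- recs[recs$class == cl & recs$status != "excluded_no_weather",
                     , drop = FALSE] %>%
        group_by(.data$week) %>%
        summarise(condemned = sum(.data$condemned),
                  total = sum(.data$total), .groups = "drop") %>%
        mutate(dlr = dead_loss_ratio(.data$condemned, .data$total))
      fg <- ledger[ledger$class == cl, , drop = FALSE] %>%
        group_by(.data$week) %>%
        summarise(foregone_usd = sum(.data$foregone_usd), .groups = "drop")
      weekly <- left_join(weekly, fg, by = "week")
      weekly$foregone_usd[is.na(weekly$foregone_usd)] <- 0
      write.csv(weekly, file.path(out_dir, paste0("figure_weekly_", cl,
                                                  ".csv")),
                row.names = FALSE)
    }

    status_count <- function(s) sum(recs$status == s)
    manifest <- c(manifest, list(
      n_records = nrow(slaughter),
      n_invalid = sum(!valid),
      n_plants = nrow(inputs$plants),
      n_plants_linked = length(unique(pww$plant_id)),
      excluded_plants = attr(pww, "excluded_plants"),
      records = list(
        modelled = status_count("modelled"),
        baseline = status_count("baseline"),
        excluded_no_weather = status_count("excluded_no_weather"),
        excluded_invalid = sum(!valid),
        excluded_out_of_range = status_count("excluded_out_of_range")
      ),
      head = list(
        total = sum(slaughter$total),
        excluded_no_weather = sum(recs$total[recs$status ==
                                               "excluded_no_weather"])
      ),
      converged = list(hi = fit_hi$converged, cold = fit_cold$converged,
                       baseline = fit_base$converged),
      outputs = list.files(out_dir)
    ))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(manifest = manifest, violations = violations,
         fits = list(hi = fit_hi, cold = fit_cold, baseline = fit_base),
         risk = list(hi = risk_hi, cold = risk_cold),
         revenue = revenue_summary, ledger = ledger,
         dlr_monthly = dlr_monthly, records = recs, truth = truth)
  }, error = function(e) {
    writeLines(paste0("INVALID RUN (failed at stage ", stage, "): ",
                      conditionMessage(e)),
               file.path(out_dir, "INVALID"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
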