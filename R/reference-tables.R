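# Published summary values from US federal slaughter-condemnation
# surveillance, 2010-2015. Included for two purposes: they are the default
# ground-truth rates of the synthetic-data generator, and they power the
# worked-example regression suite (the definitional arithmetic CR -> RR/AR/
# EIR and excess -> percent/dollar totals must reproduce the published
# derived columns from the published inputs).

#' Published condemnation rates by class and exposure category
#'
#' Model-estimated per-head "dead" condemnation rates for US swine,
#' 2010-2015, on both exposure axes. The shared baseline (minimum above
#' 50 F, weekly average 54-79 F) appears once per class with
#' `axis = "baseline"`.
#'
#' @return tibble with `class`, `axis` (`baseline`, `hi`, `min_temp`),
#'   `category`, `cr`.
#' @export
cr_reference <- function() {
  tibble::tribble(
    ~class,     ~axis,      ~category,   ~cr,
    "roaster",  "baseline", "baseline",  0.00123,
    "roaster",  "hi",       "moderate",  0.00173,
    "roaster",  "hi",       "hot",       0.00098,
    "roaster",  "hi",       "very_hot",  0.00015,
    "roaster",  "min_temp", "cool",      0.00149,
    "roaster",  "min_temp", "cold",      0.00191,
    "roaster",  "min_temp", "very_cold", 0.00271,
    "market",   "baseline", "baseline",  0.0030,
    "market",   "hi",       "moderate",  0.0038,
    "market",   "hi",       "hot",       0.0041,
    "market",   "hi",       "very_hot",  0.0035,
    "market",   "min_temp", "cool",      0.0029,
    "market",   "min_temp", "cold",      0.0033,
    "market",   "min_temp", "very_cold", 0.0043,
    "cull_sow", "baseline", "baseline",  0.0027,
    "cull_sow", "hi",       "moderate",  0.0056,
    "cull_sow", "hi",       "hot",       0.0052,
    "cull_sow", "hi",       "very_hot",  0.0061,
    "cull_sow", "min_temp", "cool",      0.0022,
    "cull_sow", "min_temp", "cold",      0.0023,
    "cull_sow", "min_temp", "very_cold", 0.0029
  )
}

#' Published excess-condemnation and foregone-revenue summary
#'
#' Per class and exposure category: increased "dead" condemnations above
#' the baseline-weeks counterfactual, foregone revenue (USD thousands),
#' head slaughtered in the category (thousands), and the published percent
#' condemned due to extreme temperature.
#'
#' @return tibble with `class`, `axis`, `category`, `increased`,
#'   `foregone_usd_k`, `head_k`, `percent`.
#' @export
excess_reference <- function() {
  tibble::tribble(
    ~class,     ~axis,      ~category,   ~increased, ~foregone_usd_k, ~head_k, ~percent,
    "roaster",  "min_temp", "very_cold",        260,            14.6,     134,    0.194,
    "roaster",  "min_temp", "cold",            2303,           124.1,    1236,    0.186,
    "roaster",  "min_temp", "cool",            1256,            71.3,     897,    0.140,
    "roaster",  "hi",       "moderate",         125,             7.9,     136,    0.092,
    "roaster",  "hi",       "hot",               62,             4.4,     161,    0.039,
    "roaster",  "hi",       "very_hot",           1,            0.05,      51,    0.001,
    "market",   "min_temp", "very_cold",      11650,          1945.1,   46109,    0.025,
    "market",   "min_temp", "cold",           46913,          8231.3,  216300,    0.022,
    "market",   "min_temp", "cool",           22790,          4210.6,  123649,    0.018,
    "market",   "hi",       "moderate",        5917,          1165.4,    8350,    0.071,
    "market",   "hi",       "hot",            10720,          2075.9,   14432,    0.074,
    "market",   "hi",       "very_hot",         283,            53.7,    2102,    0.014,
    "cull_sow", "min_temp", "very_cold",        834,           231.1,     520,    0.160,
    "cull_sow", "min_temp", "cold",            7131,          1793.6,    6057,    0.118,
    "cull_sow", "min_temp", "cool",            7500,          1982.3,    4133,    0.181,
    "cull_sow", "hi",       "moderate",         992,           262.7,     368,    0.334,
    "cull_sow", "hi",       "hot",             2275,           538.2,     682,    0.269,
    "cull_sow", "hi",       "very_hot",         814,           211.6,     154,    0.528
  )
}

#' Published monthly dead-loss ratios and average temperatures
#'
#' All-class monthly DLR (percent) and mean ambient temperature over the
#' 2010-2015 study window; the seasonal pattern (warmest and deadliest in
#' July-August) anchors the synthetic weather model.
#'
#' @return tibble with `month`, `dlr`, `avg_temp`.
#' @export
dlr_monthly_reference <- function() {
  tibble(
    month = 1:12,
    dlr = c(0.168, 0.164, 0.163, 0.161, 0.183, 0.197,
            0.228, 0.236, 0.204, 0.180, 0.176, 0.180),
    avg_temp = c(33.4, 35.9, 46.9, 56.7, 65.4, 72.9,
                 76.9, 74.5, 67.5, 56.9, 45.8, 38.5)
  )
}
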