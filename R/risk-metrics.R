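# Epidemiological summaries: condemnation rate (CR), expected incidence rate
# (EIR, per 10,000 head), attributable risk (AR, risk difference vs the
# class baseline), risk ratio (RR, with Wald 95% CI on the log scale), and
# the dead loss ratio (DLR, percent).

#' Expected incidence rate per 10,000 head
#' @param cr condemnation rate(s) per head, in \[0, 1\].
#' @return integer: `round(cr * 10000)`.
#' @export
expected_incidence <- function(cr) {
  if (any(!is.finite(cr)) || any(cr < 0 | cr > 1))
    abort_domain("cr must lie in [0, 1]")
  # half-away-from-zero on the decimal value (0.00015 -> 2), guarded
  # against binary representation error
  floor(signif(cr * 10000, 12) + 0.5)
}

#' Attributable risk (risk difference)
#'
#' Signed difference `cr_exposed - cr_baseline`; negative values mean the
#' exposure carries less risk than the class baseline.
#'
#' @param cr_exposed,cr_baseline rates per head in \[0, 1\].
#' @return numeric risk difference.
#' @export
attributable_risk <- function(cr_exposed, cr_baseline) {
  for (v in list(cr_exposed, cr_baseline))
    if (any(!is.finite(v)) || any(v < 0 | v > 1))
      abort_domain("rates must lie in [0, 1]")
  cr_exposed - cr_baseline
}

#' Risk ratio with 95% confidence interval
#'
#' `RR = cr_exposed / cr_baseline`; when a standard error for log RR is
#' supplied, a Wald interval `exp(log RR +/- 1.96 * se)` is attached.
#'
#' @param cr_exposed,cr_baseline rates per head; the baseline must be > 0.
#' @param se_log_rr optional standard error of log RR (delta method).
#' @return tibble with `rr`, `ci_lo`, `ci_hi` (CI columns `NA` without an
#'   SE).
#' @export
risk_ratio <- function(cr_exposed, cr_baseline, se_log_rr = NULL) {
  if (any(cr_baseline <= 0)) abort_domain("baseline rate must be positive")
  rr <- cr_exposed / cr_baseline
  if (is.null(se_log_rr)) {
    tibble(rr = rr, ci_lo = NA_real_, ci_hi = NA_real_)
  } else {
    z <- qnorm(0.975)
    tibble(rr = rr,
           ci_lo = exp(log(rr) - z * se_log_rr),
           ci_hi = exp(log(rr) + z * se_log_rr))
  }
}

#' Dead loss ratio (percent)
#'
#' Condemned head divided by total head slaughtered, times 100.
#'
#' @param condemned,total head counts; `total >= 1` and
#'   `0 <= condemned <= total`.
#' @return percent in \[0, 100\].
#' @export
dead_loss_ratio <- function(condemned, total) {
  if (any(total < 1)) abort_domain("total must be >= 1")
  if (any(condemned < 0 | condemned > total))
    abort_domain("condemned must lie in [0, total]")
  condemned / total * 100
}

#' Risk table from a fitted model
#'
#' One row per class x category with CR, EIR, AR, RR, and the Wald 95% CI
#' for RR. Under the nested coding the log RR against the class baseline is
#' a single coefficient, so its delta-method SE is read straight off the
#' coefficient covariance. Baseline rows carry `RR = 1` and no AR.
#'
#' @param fit a converged `zinb_fit` with a nested class/category design.
#' @param classes,categories cells to tabulate (defaults: all in the
#'   design).
#' @return tibble: `class`, `category`, `cr`, `eir`, `ar`, `rr`, `rr_lo`,
#'   `rr_hi`.
#' @export
build_risk_table <- function(fit, classes = NULL, categories = NULL) {
  stopifnot(inherits(fit, "zinb_fit"))
  if (!fit$converged) abort_domain("fit did not converge")
  d <- fit$design
  if (is.null(classes)) classes <- unique(d$class)
  rows <- list()
  for (cl in classes) {
    cats <- d$category[d$class == cl]
    if (!is.null(categories))
      cats <- intersect(c(fit$baseline_category, categories), cats)
    cr_base <- predict_rate(fit, cl, fit$baseline_category)
    for (ct in cats) {
      cr <- predict_rate(fit, cl, ct)
      if (ct == fit$baseline_category) {
        rows[[length(rows) + 1L]] <- tibble(
          class = cl, category = ct, cr = cr,
          eir = expected_incidence(cr), ar = NA_real_,
          rr = 1, rr_lo = NA_real_, rr_hi = NA_real_)
      } else {
        term <- d$term[d$class == cl & d$category == ct]
        se <- sqrt(fit$vcov_beta[term, term])
        rat <- risk_ratio(cr, cr_base, se)
        rows[[length(rows) + 1L]] <- tibble(
          class = cl, category = ct, cr = cr,
          eir = expected_incidence(cr),
          ar = attributable_risk(cr, cr_base),
          rr = rat$rr, rr_lo = rat$ci_lo, rr_hi = rat$ci_hi)
      }
    }
  }
  bind_rows(rows)
}

#' Risk table from plain condemnation rates
#'
#' The same derivation applied to a table of rates rather than a fitted
#' model — e.g. to recompute RR/AR/EIR columns from a published CR column as
#' a worked example. No confidence intervals (no covariance available).
#'
#' @param rates tibble with `class`, `category`, `cr`.
#' @param baseline_category reference category label.
#' @return tibble as in [build_risk_table()] minus the CI columns.
#' @export
risk_table_from_cr <- function(rates, baseline_category = "baseline") {
  stopifnot(all(c("class", "category", "cr") %in% names(rates)))
  rates %>%
    group_by(.data$class) %>%
    mutate(cr_base = .data$cr[.data$category == baseline_category][1]) %>%
    ungroup() %>%
    mutate(
      eir = expected_incidence(.data$cr),
      ar = ifelse(.data$category == baseline_category, NA_real_,
                  attributable_risk(.data$cr, .data$cr_base)),
      rr = .data$cr / .data$cr_base
    ) %>%
    select(all_of(c("class", "category", "cr", "eir", "ar", "rr")))
}

#' Monthly dead-loss-ratio table
#'
#' @param records weekly records with `week`, `condemned`, `total` (and
#'   optionally `class` for a per-class breakdown).
#' @param by_class also disaggregate by swine class.
#' @return tibble with `month`, (`class`,) `condemned`, `total`, `dlr`.
#' @export
dlr_table <- function(records, by_class = FALSE) {
  records$month <- iso_week_month(records$week)$month
  keys <- if (by_class) c("month", "class") else "month"
  records %>%
    group_by(across(all_of(keys))) %>%
    summarise(condemned = sum(.data$condemned), total = sum(.data$total),
              .groups = "drop") %>%
    mutate(dlr = dead_loss_ratio(.data$condemned, .data$total))
}
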