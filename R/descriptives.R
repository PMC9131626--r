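# Descriptive summaries of age at first marriage, overall and by
# covariate group. Ages are summarized over observed event cases only
# (the convention of retrospective DHS tables); percentages use the
# full-sample denominator.

#' Overall age-at-first-marriage summary
#'
#' Counts, percentage married, and mean/median/min/max observed marriage
#' age (event cases only; `NA` if no events).
#'
#' @param data data.frame with `time` and `event` columns.
#' @return A one-row data.frame: `n_total`, `n_married`, `pct_married`,
#'   `mean_age`, `median_age`, `min_age`, `max_age`.
#' @export
overall_summary <- function(data) {
  stopifnot(is.data.frame(data), nrow(data) > 0,
            all(c("time", "event") %in% names(data)))
  ev <- data$event == 1
  ages <- data$time[ev]
  data.frame(
    n_total = nrow(data), n_married = sum(ev),
    pct_married = 100 * sum(ev) / nrow(data),
    mean_age = if (any(ev)) mean(ages) else NA_real_,
    median_age = if (any(ev)) median(ages) else NA_real_,
    min_age = if (any(ev)) min(ages) else NA_real_,
    max_age = if (any(ev)) max(ages) else NA_real_)
}

# Kaplan-Meier median (optional alternative to the observed-case median)
km_median <- function(time, event) {
  if (!requireNamespace("survival", quietly = TRUE))
    stop("the Kaplan-Meier median option requires the 'survival' package")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  unname(summary(sf)$table["median"])
}

#' Group-wise age-at-first-marriage summary
#'
#' One row per category of `covariate`: group size and its percentage of
#' the FULL sample, number married and its percentage of the full sample
#' (so married percentages sum to the overall married percentage), and
#' mean/median marriage age among event cases.
#'
#' @param data data.frame with `time`, `event` and the covariate column.
#' @param covariate name of a categorical column in `data`.
#' @param km logical: report Kaplan-Meier medians instead of
#'   observed-case medians (requires the survival package; default off).
#' @return A data.frame with one row per category.
#' @export
describe_by_group <- function(data, covariate, km = FALSE) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  if (!covariate %in% names(data))
    stop("unknown covariate: '", covariate, "'")
  x <- data[[covariate]]
  levs <- if (is.factor(x)) levels(x) else unique(as.character(x))
  n_all <- nrow(data)
  rows <- lapply(levs, function(g) {
    sub <- data[as.character(x) == g, , drop = FALSE]
    ev <- sub$event == 1
    ages <- sub$time[ev]
    med <- if (!any(ev)) NA_real_
           else if (km) km_median(sub$time, sub$event) else median(ages)
    data.frame(covariate = covariate, group = g,
               n_total = nrow(sub), pct_total = 100 * nrow(sub) / n_all,
               n_married = sum(ev),
               pct_married_of_total = 100 * sum(ev) / n_all,
               mean_age = if (any(ev)) mean(ages) else NA_real_,
               median_age = med, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
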