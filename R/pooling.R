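#' Select and combine surveys into a country estimate
#'
#' Applies the country decision tree to a set of survey estimates sharing
#' one country:
#'
#' 1. If any nationally representative estimate exists (a single national
#'    survey, or a series declared national in its metadata), the most
#'    recent one is taken alone.
#' 2. Otherwise the most recent subnational survey anchors the estimate,
#'    and every other subnational survey completed within 3 years before
#'    it (boundary inclusive: a 2019 anchor pools 2016 but not 2015) is
#'    pooled with it by inverse-variance weighting
#'    ([pool_inverse_variance()]).
#'
#' Ties on completion year are broken by larger sample size, then by
#' lexicographic survey id. More recent surveys and national sampling
#' frames are thereby always prioritised, and adding an older survey can
#' never change a selection made from newer ones.
#'
#' @param estimates a tibble with one row per survey: the estimate columns
#'   (`value`, `se`, ...) plus metadata columns `survey_id`, `country`,
#'   `year`, `scope`.
#' @return a one-row tibble: the selected or pooled estimate columns plus
#'   `method` (`SINGLE_NATIONAL`, `POOLED_NATIONAL_SERIES`,
#'   `SINGLE_SUBNATIONAL`, `POOLED_SUBNATIONAL`) and `provenance`
#'   (contributing survey ids, comma-separated, anchor first).
#' @examples
#' ests <- tibble::tibble(
#'   survey_id = c("bt2009", "bt2017"), country = "Bhutan",
#'   year = c(2009, 2017), scope = "NATIONAL",
#'   value = c(25.3, 40.4), se = c(3.06, 2.63), n_examined = c(3000, 3200))
#' select_country_surveys(ests)
#' @export
select_country_surveys <- function(estimates) {
  est <- tibble::as_tibble(estimates)
  if (nrow(est) == 0) stop("no candidate surveys supplied", call. = FALSE)
  need <- c("survey_id", "year", "scope", "value", "se")
  missing_cols <- setdiff(need, names(est))
  if (length(missing_cols) > 0) {
    stop("estimates table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("country" %in% names(est) &&
      dplyr::n_distinct(est$country) > 1) {
    stop("all candidate surveys must share one country", call. = FALSE)
  }
  if (!"n_examined" %in% names(est)) est$n_examined <- NA_real_
  rank_order <- order(-est$year, -xtfrm(dplyr::coalesce(est$n_examined, 0)),
                      est$survey_id)
  est <- est[rank_order, ]

  national <- dplyr::filter(est, .data$scope == "NATIONAL")
  if (nrow(national) > 0) {
    sel <- national[1, ]
    method <- if ("is_series" %in% names(sel) && isTRUE(sel$is_series[1]))
      "POOLED_NATIONAL_SERIES" else "SINGLE_NATIONAL"
    out <- sel
  } else {
    anchor <- est[1, ]
    window <- dplyr::filter(est, .data$year >= anchor$year - 3)
    if (nrow(window) > 1) {
      pooled <- pool_inverse_variance(window)
      out <- pooled
      out$survey_id <- NA_character_
      for (col in c("country", "indicator", "sex", "config")) {
        if (col %in% names(window)) out[[col]] <- window[[col]][1]
      }
      out$year <- anchor$year
      out$scope <- "SUBNATIONAL"
      method <- "POOLED_SUBNATIONAL"
      sel <- window
    } else {
      out <- anchor
      method <- "SINGLE_SUBNATIONAL"
      sel <- anchor
    }
  }
  out$method <- method
  out$provenance <- paste(sel$survey_id, collapse = ",")
  cols <- intersect(c("country", "indicator", "sex", "value", "se",
                      "ci_low", "ci_high", "n_examined", "year", "scope",
                      "config", "method", "provenance"), names(out))
  out[, cols]
}

#' Fixed-effect inverse-variance pooling
#'
#' Combines estimates with weights `1 / se^2`: the pooled value is the
#' weighted mean and the pooled standard error is `sqrt(1 / sum(weights))`.
#' The pooled value always lies within the range of the inputs and the
#' pooled SE never exceeds the smallest contributing SE. Used for
#' combining subnational estimates within a country; between-study
#' heterogeneity is the business of [pool_random_effects()].
#'
#' @param estimates a tibble with columns `value` and `se` (percent scale);
#'   all `se` must be strictly positive — a zero-variance estimate would
#'   take infinite weight and is rejected with a diagnostic.
#' @return a one-row tibble with `value`, `se`, `ci_low`, `ci_high`,
#'   `n_examined` (summed if present), `k_pooled`.
#' @examples
#' pool_inverse_variance(tibble::tibble(value = c(20, 40), se = c(2, 4)))
#' @export
pool_inverse_variance <- function(estimates) {
  est <- tibble::as_tibble(estimates)
  stopifnot(all(c("value", "se") %in% names(est)))
  if (any(is.na(est$value) | is.na(est$se))) {
    stop("cannot pool undefined estimates", call. = FALSE)
  }
  if (any(est$se <= 0)) {
    stop("zero-variance estimate(s) rejected from pooling: se must be > 0 ",
         "(offending value ", est$value[est$se <= 0][1], ")", call. = FALSE)
  }
  if (nrow(est) == 1) {
    return(dplyr::mutate(est, k_pooled = 1L))
  }
  u <- 1 / est$se^2
  value <- sum(u * est$value) / sum(u)
  se <- sqrt(1 / sum(u))
  tibble::tibble(
    value = value, se = se,
    ci_low = max(0, value - 1.96 * se),
    ci_high = min(100, value + 1.96 * se),
    n_examined = if ("n_examined" %in% names(est))
      sum(est$n_examined) else NA_real_,
    k_pooled = nrow(est)
  )
}

#' Summarise country estimates by group
#'
#' Median, IQR, range, survey count and year span of country estimates
#' within groups (e.g. WHO region or World Bank income stratum labels
#' carried in survey metadata). Quartiles use linear interpolation between
#' order statistics (`stats::quantile` type 7). Groups with no estimates
#' are omitted.
#'
#' @param estimates a tibble of country estimates with a `value` column, a
#'   grouping column, and optionally `year`.
#' @param group name of the grouping column (string).
#' @return a tibble with one row per group: `median`, `q1`, `q3`, `min`,
#'   `max`, `n`, `year_min`, `year_max`.
#' @export
group_summary <- function(estimates, group) {
  est <- tibble::as_tibble(estimates)
  stopifnot(group %in% names(est), "value" %in% names(est))
  est <- dplyr::filter(est, !is.na(.data[[group]]), !is.na(.data$value))
  if (!"year" %in% names(est)) est$year <- NA_integer_
  est |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      median = stats::median(.data$value),
      q1 = unname(stats::quantile(.data$value, 0.25, type = 7)),
      q3 = unname(stats::quantile(.data$value, 0.75, type = 7)),
      min = min(.data$value),
      max = max(.data$value),
      n = dplyr::n(),
      year_min = suppressWarnings(min(.data$year, na.rm = TRUE)),
      year_max = suppressWarnings(max(.data$year, na.rm = TRUE)),
      .groups = "drop"
    )
}
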