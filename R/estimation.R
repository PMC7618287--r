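#' Post-stratification adjustment factors
#'
#' For each of the eight age-sex strata, the weight `w = N / n`: the census
#' population count divided by the number examined in the sample. Applying
#' these weights to stratum numerators and denominators re-expresses the
#' sample on the age-sex structure of the source population, which is the
#' point of post-stratification. (Note the convention: population over
#' examined, so under-sampled strata are up-weighted.)
#'
#' A stratum with census population but nobody examined has an undefined
#' weight. By default (`empty_stratum = "collapse"`) its population count
#' is folded into the adjacent age band of the same sex (towards the
#' younger band, except 50-59 which folds upward) and a message is logged;
#' `empty_stratum = "error"` makes it a hard error instead. The collapse
#' conserves the total population per sex.
#'
#' @param survey a participant tibble.
#' @param population an 8-row population tibble ([read_population()]).
#' @param empty_stratum `"collapse"` (default) or `"error"`.
#' @param sexes which sexes to weight (both by default; one sex for
#'   sex-restricted, age-adjusted-only estimates).
#' @return a tibble with columns `sex`, `age_band`, `n_pop`, `n_examined`,
#'   `weight`.
#' @export
adjustment_factors <- function(survey, population,
                               empty_stratum = c("collapse", "error"),
                               sexes = c("F", "M")) {
  empty_stratum <- match.arg(empty_stratum)
  pop <- validate_population(population, sexes = sexes)
  d <- tibble::as_tibble(survey)
  samp <- d |>
    dplyr::count(sex = .data$sex, age_band = age_band(.data$age),
                 name = "n_examined")
  w <- pop |>
    dplyr::rename(n_pop = "count") |>
    dplyr::left_join(samp, by = c("sex", "age_band")) |>
    dplyr::mutate(n_examined = dplyr::coalesce(.data$n_examined, 0L)) |>
    dplyr::arrange(.data$sex, match(.data$age_band, age_bands))

  empty <- w$n_examined == 0 & w$n_pop > 0
  if (any(empty)) {
    if (empty_stratum == "error") {
      stop("stratum with population but no examined participants: ",
           paste(w$sex[empty], w$age_band[empty], collapse = "; "),
           call. = FALSE)
    }
    for (i in which(empty)) {
      band_i <- match(w$age_band[i], age_bands)
      neighbours <- order(abs(seq_along(age_bands) - band_i))[-1]
      for (j in neighbours) {
        k <- which(w$sex == w$sex[i] & w$age_band == age_bands[j] &
                     w$n_examined > 0)
        if (length(k) == 1) {
          message("collapsing empty stratum ", w$sex[i], " ", w$age_band[i],
                  " into ", w$sex[i], " ", age_bands[j])
          w$n_pop[k] <- w$n_pop[k] + w$n_pop[i]
          w$n_pop[i] <- 0
          break
        }
      }
      if (w$n_pop[i] > 0) {
        stop("no non-empty stratum of sex ", w$sex[i],
             " to collapse ", w$age_band[i], " into", call. = FALSE)
      }
    }
  }
  dplyr::mutate(w, weight = ifelse(.data$n_examined > 0,
                                   .data$n_pop / .data$n_examined, NA_real_))
}

#' Cluster-adjusted standard error of a ratio estimate
#'
#' Standard error of the combined ratio `r = sum(y) / sum(x)` over cluster
#' totals `(y_i, x_i)`, on the percent scale:
#'
#' \deqn{SE = 100 \sqrt{\frac{c}{c-1} \sum_i (y_i - r x_i)^2} \Big/ \sum_i x_i}
#'
#' This is the classical ratio-estimator variance for cluster-sample health
#' surveys (equivalently `(1/xbar) * sqrt(sum((y_i - r x_i)^2) / (c(c-1)))`
#' with `xbar` the mean cluster denominator). It accounts for both the
#' clustering of the sample and between-cluster variability in the
#' denominator, and is conservative relative to the exact binomial.
#' Clusters contributing nothing to the denominator enter as `(0, 0)` pairs
#' and stay in `c`: the cluster count is a property of the design.
#'
#' @param y numeric vector of per-cluster (weighted) numerator totals.
#' @param x numeric vector of per-cluster (weighted) denominator totals.
#' @return the standard error in percentage points; `NA` if `sum(x) == 0`.
#' @examples
#' cluster_se(c(2, 4, 6), c(10, 10, 10))  # 11.547
#' @export
cluster_se <- function(y, x) {
  stopifnot(length(y) == length(x), all(is.finite(y)), all(is.finite(x)))
  c_n <- length(x)
  if (c_n < 2) {
    stop("design error: at least 2 clusters are required", call. = FALSE)
  }
  sx <- sum(x)
  if (sx <= 0) return(NA_real_)
  r <- sum(y) / sx
  100 * sqrt(c_n / (c_n - 1) * sum((y - r * x)^2)) / sx
}

#' Post-stratified coverage estimate with cluster-adjusted CI
#'
#' Computes CSC and/or eCSC for a survey: participants are classified
#' ([classify_participants()]), each receives the post-stratification
#' weight of their age-sex stratum ([adjustment_factors()]), weighted
#' numerator/denominator totals are formed per cluster, and the estimate is
#' `100 * sum(w * num) / sum(w * den)` with standard error from
#' [cluster_se()] applied to the per-cluster weighted pairs — so the SE
#' reflects both the weighting and the clustering. The 95% CI is the
#' normal approximation `value +/- 1.96 * SE`, clipped to `[0, 100]`.
#'
#' Sex-restricted estimates (`sex = "F"` or `"M"`) use only that sex's
#' participants and population strata, i.e. they are age-adjusted only.
#'
#' @param survey a participant tibble.
#' @param population population tibble ([read_population()] format; 5-year
#'   bands accepted).
#' @param cfg an [indicator_config()].
#' @param indicator `"eCSC"`, `"CSC"`, or both (default).
#' @param sex `"ALL"` (default), `"F"`, or `"M"`.
#' @param empty_stratum passed to [adjustment_factors()].
#' @return a tibble with one row per requested indicator: `indicator`,
#'   `sex`, `value`, `se`, `ci_low`, `ci_high` (percent), `n_examined`,
#'   `n_clusters`, `num_weighted`, `den_weighted`, `config`. A zero
#'   weighted denominator yields `NA` value and CI (an undefined estimate,
#'   not 0 or 100).
#' @examples
#' sim <- simulate_raab_survey(raab_scenario(n_clusters = 10,
#'                                           cluster_size = 50), seed = 7)
#' coverage_estimate(sim$survey, sim$population)
#' @export
coverage_estimate <- function(survey, population, cfg = indicator_config(),
                              indicator = c("CSC", "eCSC"), sex = "ALL",
                              empty_stratum = "collapse") {
  indicator <- match.arg(indicator, several.ok = TRUE)
  stopifnot(length(sex) == 1L, sex %in% c("ALL", "F", "M"))
  cl <- classify_participants(survey, cfg)
  sexes <- if (sex == "ALL") c("F", "M") else sex
  if (sex != "ALL") {
    cl <- dplyr::filter(cl, .data$sex == !!sex)
    if (nrow(cl) == 0) {
      stop("no participants of sex ", sex, call. = FALSE)
    }
  }
  w <- adjustment_factors(cl, population, empty_stratum = empty_stratum,
                          sexes = sexes)
  cl <- dplyr::left_join(
    cl, dplyr::select(w, "sex", "age_band", "weight"),
    by = c("sex", "age_band"))

  clusters <- sort(unique(cl$cluster_id))
  per_cluster <- cl |>
    dplyr::group_by(cluster_id = .data$cluster_id) |>
    dplyr::summarise(
      den = sum(.data$weight * .data$in_denom),
      csc = sum(.data$weight * .data$in_csc_num),
      ecsc = sum(.data$weight * .data$in_ecsc_num),
      .groups = "drop"
    )

  one <- function(ind) {
    ycol <- if (ind == "CSC") "csc" else "ecsc"
    y <- per_cluster[[ycol]]
    x <- per_cluster$den
    num_w <- sum(y); den_w <- sum(x)
    if (den_w <= 0) {
      value <- se <- lo <- hi <- NA_real_
    } else {
      value <- 100 * num_w / den_w
      se <- cluster_se(y, x)
      lo <- max(0, value - 1.96 * se)
      hi <- min(100, value + 1.96 * se)
    }
    tibble::tibble(
      indicator = ind, sex = sex, value = value, se = se,
      ci_low = lo, ci_high = hi,
      n_examined = nrow(cl), n_clusters = length(clusters),
      num_weighted = num_w, den_weighted = den_w,
      config = config_label(cfg)
    )
  }
  dplyr::bind_rows(lapply(indicator, one))
}

#' Relative quality gap between CSC and eCSC
#'
#' The share of accessed cataract surgery that failed the good-outcome
#' threshold: `100 * (CSC - eCSC) / CSC`, in percent. Lower values reflect
#' better quality. Reported to one decimal place in tables, computed at
#' full precision here.
#'
#' @param csc,ecsc coverage values in percent, `ecsc <= csc` elementwise.
#' @return the relative quality gap in percent; `NA` where `csc` is 0.
#' @examples
#' quality_gap(65.7, 58.6)  # 10.8
#' quality_gap(14.3, 3.8)   # 73.4
#' @export
quality_gap <- function(csc, ecsc) {
  stopifnot(is.numeric(csc), is.numeric(ecsc), length(csc) == length(ecsc))
  bad <- !is.na(csc) & !is.na(ecsc) & ecsc > csc
  if (any(bad)) {
    stop("eCSC cannot exceed CSC (violated at position ",
         which(bad)[1], ")", call. = FALSE)
  }
  ifelse(!is.na(csc) & csc > 0, 100 * (csc - ecsc) / csc, NA_real_)
}

#' Coverage estimates over a grid of thresholds
#'
#' One estimate per (surgical threshold, outcome threshold) pair. For a
#' fixed outcome threshold, relaxing the surgical threshold from worse
#' than 3/60 towards worse than 6/12 grows the denominator (more eyes
#' count as needing surgery) while the numerator is unchanged, so eCSC is
#' non-increasing along that direction.
#'
#' @inheritParams coverage_estimate
#' @param surgical_thresholds character vector of surgical cuts.
#' @param outcome_thresholds character vector of outcome cuts.
#' @param ... passed to [indicator_config()] (e.g. `unilateral_rule`).
#' @return a tibble of class `eyecover_threshold_matrix` with columns
#'   `surgical_threshold`, `outcome_threshold` plus the estimate columns.
#' @export
threshold_matrix <- function(survey, population,
                             surgical_thresholds = c("3/60", "6/60",
                                                     "6/18", "6/12"),
                             outcome_thresholds = c("6/18", "6/12"),
                             indicator = "eCSC", sex = "ALL", ...) {
  grid <- tidyr::expand_grid(surgical_threshold = surgical_thresholds,
                             outcome_threshold = outcome_thresholds)
  out <- purrr::pmap_dfr(grid, function(surgical_threshold,
                                        outcome_threshold) {
    cfg <- indicator_config(surgical_threshold, outcome_threshold, ...)
    est <- coverage_estimate(survey, population, cfg,
                             indicator = indicator, sex = sex)
    dplyr::mutate(est, surgical_threshold = surgical_threshold,
                  outcome_threshold = outcome_threshold,
                  .before = 1)
  })
  class(out) <- c("eyecover_threshold_matrix", class(out))
  out
}
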