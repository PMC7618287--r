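#' Format an estimate in publication style
#'
#' Renders "value% (95% CI low-high)" with one-decimal rounding, e.g.
#' `"70.3% (95% CI 65.8-74.9)"`. The journal-style middle-dot decimal
#' separator is available behind `style = "journal"`; the default is
#' plain ASCII.
#'
#' @param value,ci_low,ci_high numeric vectors in percent.
#' @param style `"ascii"` (default) or `"journal"`.
#' @return a character vector.
#' @examples
#' format_estimate(70.34, 65.82, 74.91)
#' @export
format_estimate <- function(value, ci_low, ci_high, style = c("ascii",
                                                              "journal")) {
  style <- match.arg(style)
  out <- sprintf("%.1f%% (95%% CI %.1f-%.1f)", value, ci_low, ci_high)
  out[is.na(value)] <- NA_character_
  if (style == "journal") {
    out <- gsub("(?<=\\d)\\.(?=\\d)", "·", out, perl = TRUE)
    out <- gsub("-(?=\\d)", "–", out, perl = TRUE)
  }
  out
}

#' Run the full coverage pipeline on a set of surveys
#'
#' Drives every stage on already-loaded data: classification and
#' estimation per survey ([coverage_estimate()]), quality gaps
#' ([quality_gap()]), country selection and pooling
#' ([select_country_surveys()]), grouped summaries ([group_summary()]),
#' the threshold matrix ([threshold_matrix()]) and, when both sexes are
#' present, the sex-disparity meta-analysis ([sex_effect()],
#' [pool_random_effects()]). Deterministic given its inputs; the seed in
#' the manifest records the run configuration only.
#'
#' @param surveys a named list; each element is a list with components
#'   `survey` (participant tibble), `population` (stratum table) and
#'   `meta` (one-row metadata tibble, see [read_survey_meta()]).
#' @param cfg an [indicator_config()].
#' @param group_labels which metadata columns to summarise country
#'   estimates by.
#' @param run_threshold_matrix,run_sex_gap stage toggles.
#' @return a list of tibbles: `estimates` (per survey x indicator, with
#'   quality gaps on the CSC rows), `countries`, `group_summaries`,
#'   `thresholds` (per survey), `sex_effects`, `sex_pooled`, and
#'   `manifest`.
#' @export
run_coverage_pipeline <- function(surveys, cfg = indicator_config(),
                                  group_labels = c("region_label",
                                                   "income_label"),
                                  run_threshold_matrix = TRUE,
                                  run_sex_gap = TRUE) {
  stopifnot(length(surveys) > 0)

  per_survey <- purrr::map_dfr(surveys, function(s) {
    est <- coverage_estimate(s$survey, s$population, cfg)
    dplyr::bind_cols(s$meta[rep(1, nrow(est)), ], est)
  })
  wide <- tidyr::pivot_wider(
    dplyr::select(per_survey, "survey_id", "indicator", "value"),
    names_from = "indicator", values_from = "value")
  wide$quality_gap <- quality_gap(wide$CSC, wide$eCSC)
  estimates <- dplyr::left_join(
    per_survey, dplyr::select(wide, "survey_id", "quality_gap"),
    by = "survey_id")
  estimates$quality_gap[estimates$indicator != "CSC"] <- NA_real_

  countries <- estimates |>
    dplyr::filter(.data$indicator == "eCSC") |>
    dplyr::group_by(country = .data$country) |>
    dplyr::group_modify(~ select_country_surveys(.x)) |>
    dplyr::ungroup()

  group_summaries <- purrr::map_dfr(
    intersect(group_labels, names(estimates)), function(g) {
      meta_g <- estimates |>
        dplyr::filter(.data$indicator == "eCSC") |>
        dplyr::distinct(.data$country, .data[[g]])
      joined <- dplyr::left_join(countries, meta_g, by = "country")
      out <- group_summary(joined, g)
      if (nrow(out) == 0) return(out)
      names(out)[1] <- "group"
      dplyr::mutate(out, label = g, .before = 1)
    })

  thresholds <- if (run_threshold_matrix) {
    purrr::map_dfr(surveys, function(s) {
      tm <- threshold_matrix(s$survey, s$population,
                             outcome_thresholds = "6/12",
                             unilateral_rule = cfg$unilateral_rule,
                             require_cataract_cause =
                               cfg$require_cataract_cause)
      dplyr::mutate(tm, survey_id = s$meta$survey_id, .before = 1)
    })
  } else NULL

  sex_effects <- sex_pooled <- NULL
  if (run_sex_gap) {
    sex_effects <- purrr::map_dfr(surveys, function(s) {
      both <- all(c("F", "M") %in% s$survey$sex)
      if (!both) return(NULL)
      eff <- sex_effect(s$survey, s$population, cfg, indicator = "eCSC")
      dplyr::mutate(eff, survey_id = s$meta$survey_id, .before = 1)
    })
    if (!is.null(sex_effects) && nrow(sex_effects) >= 2) {
      rd <- dplyr::filter(sex_effects, .data$measure == "RD")
      rr <- dplyr::filter(sex_effects, .data$measure == "RR")
      sex_pooled <- dplyr::bind_rows(
        if (nrow(rd) >= 2)
          dplyr::mutate(glance(pool_random_effects(rd)), measure = "RD",
                        .before = 1),
        if (nrow(rr) >= 2)
          dplyr::mutate(glance(pool_random_effects(rr, log_scale = TRUE)),
                        measure = "RR", .before = 1)
      )
    }
  }

  manifest <- tibble::tibble(
    n_surveys = length(surveys),
    config = config_label(cfg),
    run_time = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("eyecover"))
  )
  list(estimates = estimates, countries = countries,
       group_summaries = group_summaries, thresholds = thresholds,
       sex_effects = sex_effects, sex_pooled = sex_pooled,
       manifest = manifest)
}

#' Write the pipeline bundle to a directory of CSV tables
#'
#' One file per table (`estimates.csv`, `countries.csv`,
#' `group_summaries.csv`, `thresholds.csv`, `sex_effects.csv`,
#' `sex_pooled.csv`, `manifest.csv`), skipping stages that did not run.
#'
#' @param bundle result of [run_coverage_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(bundle)) {
    tab <- bundle[[nm]]
    if (is.null(tab) || nrow(tab) == 0) next
    readr::write_csv(tibble::as_tibble(tab),
                     file.path(dir, paste0(nm, ".csv")), na = "NA",
                     progress = FALSE)
  }
  invisible(dir)
}

#' Plot a threshold matrix
#'
#' Coverage against the cataract surgical threshold, one line per outcome
#' threshold — the tabular analogue of plotting the spread of eCSC across
#' surgical thresholds.
#'
#' @param object an `eyecover_threshold_matrix` ([threshold_matrix()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eyecover_threshold_matrix <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$surgical_threshold <- factor(d$surgical_threshold,
                                 levels = c("3/60", "6/60", "6/18", "6/12"))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$surgical_threshold, y = .data$value,
    colour = .data$outcome_threshold,
    group = paste(.data$outcome_threshold, .data$indicator))) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high,
                   fill = .data$outcome_threshold),
      alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cataract surgical threshold (worse than)",
                  y = paste0(unique(d$indicator), " (%)"),
                  colour = "good outcome", fill = "good outcome") +
    ggplot2::theme_minimal()
}
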