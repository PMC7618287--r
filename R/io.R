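#' Read a participant-level survey file
#'
#' Reads a comma-delimited, UTF-8 survey export with one row per examined
#' participant. The canonical column schema is:
#' `participant_id, cluster_id, age, sex, r_lens, l_lens, r_pva, l_pva,
#' r_bcva, l_bcva, r_cause, l_cause`, with sex in `{F, M}`, lens status in
#' [lens_levels], acuity in [va_levels] and cause in [cause_levels]; empty
#' cells and `NA` mark missing values. `col_map` can translate external
#' header names onto this schema (`col_map = c(r_lens = "lens_right")`).
#'
#' Rows violating hard constraints (age below 50, unknown codes, missing
#' identifiers, duplicated participant ids) are rejected with row-numbered
#' diagnostics; the rejected diagnostics are attached as the
#' `"rejected"` attribute and reported in a warning. A file with fewer than
#' two distinct clusters after rejection is a design error because the
#' cluster-sample variance formula is undefined. A best-corrected acuity
#' worse than the presenting acuity in the same eye is logged as a soft
#' warning only, since field data can contain it.
#'
#' @param path path to the survey CSV file.
#' @param col_map optional named character vector mapping canonical column
#'   names to the file's header names.
#' @return a tibble of validated participants (class `eyecover_survey`),
#'   with attribute `rejected` (a tibble of row/column/reason diagnostics).
#' @seealso [write_survey()], [classify_participants()]
#' @export
read_survey <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      ext <- col_map[[canon]]
      if (ext %in% names(raw)) names(raw)[names(raw) == ext] <- canon
    }
  }
  validate_survey(raw, source = path)
}

survey_columns <- c("participant_id", "cluster_id", "age", "sex",
                    "r_lens", "l_lens", "r_pva", "l_pva",
                    "r_bcva", "l_bcva", "r_cause", "l_cause")

#' Validate a participant table
#'
#' Applies the survey schema and row-level invariants to an in-memory data
#' frame (the same checks [read_survey()] performs after parsing).
#'
#' @param data a data frame with the canonical survey columns.
#' @param source label used in messages.
#' @return a validated `eyecover_survey` tibble.
#' @export
validate_survey <- function(data, source = "survey data") {
  missing_cols <- setdiff(survey_columns, names(data))
  if (length(missing_cols) > 0) {
    stop("schema error in ", source, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- tibble::as_tibble(data)[survey_columns]
  d$age <- suppressWarnings(as.numeric(d$age))
  d$.row <- seq_len(nrow(d))

  reject <- function(rows, column, reason) {
    tibble::tibble(row = rows, column = column, reason = reason)
  }
  diags <- list()
  bad_code <- function(x, levels) !is.na(x) & x != "NA" & !(x %in% levels)

  diags[[length(diags) + 1L]] <-
    reject(d$.row[is.na(d$participant_id) | d$participant_id == ""],
           "participant_id", "missing participant id")
  diags[[length(diags) + 1L]] <-
    reject(d$.row[is.na(d$cluster_id) | d$cluster_id == ""],
           "cluster_id", "missing cluster id")
  diags[[length(diags) + 1L]] <-
    reject(d$.row[is.na(d$age) | d$age < 50], "age",
           "age must satisfy age >= 50")
  diags[[length(diags) + 1L]] <-
    reject(d$.row[!is.na(d$sex) & !(d$sex %in% c("F", "M"))], "sex",
           "sex must be F or M")
  diags[[length(diags) + 1L]] <-
    reject(d$.row[is.na(d$sex)], "sex", "missing sex")
  for (col in c("r_lens", "l_lens")) {
    diags[[length(diags) + 1L]] <-
      reject(d$.row[bad_code(d[[col]], lens_levels)], col,
             "unknown lens status code")
  }
  for (col in c("r_pva", "l_pva", "r_bcva", "l_bcva")) {
    diags[[length(diags) + 1L]] <-
      reject(d$.row[bad_code(d[[col]], va_levels)], col,
             "unknown visual acuity code")
  }
  for (col in c("r_cause", "l_cause")) {
    diags[[length(diags) + 1L]] <-
      reject(d$.row[bad_code(d[[col]], cause_levels)], col,
             "unknown cause code")
  }
  dup <- d$.row[duplicated(d$participant_id) & !is.na(d$participant_id)]
  diags[[length(diags) + 1L]] <-
    reject(dup, "participant_id", "duplicate participant id")

  rejected <- dplyr::distinct(dplyr::bind_rows(diags))
  keep <- !(d$.row %in% rejected$row)
  d <- d[keep, ]
  if (nrow(rejected) > 0) {
    warning(nrow(rejected), " invalid value(s) in ", source, "; ",
            length(unique(rejected$row)), " row(s) rejected (first: row ",
            min(rejected$row), ", ", rejected$reason[which.min(rejected$row)],
            ")", call. = FALSE)
  }
  if (nrow(d) == 0) {
    stop("no valid participant rows in ", source, call. = FALSE)
  }
  if (dplyr::n_distinct(d$cluster_id) < 2) {
    stop("design error in ", source,
         ": at least 2 distinct clusters are required", call. = FALSE)
  }

  # normalise "NA" strings to real NA and soft-check bcva <= pva
  for (col in c("r_lens", "l_lens", "r_pva", "l_pva", "r_bcva", "l_bcva",
                "r_cause", "l_cause")) {
    d[[col]][d[[col]] == "NA"] <- NA_character_
  }
  soft <- (va_rank(d$r_bcva) > va_rank(d$r_pva)) |
          (va_rank(d$l_bcva) > va_rank(d$l_pva))
  n_soft <- sum(soft, na.rm = TRUE)
  if (n_soft > 0) {
    message(n_soft, " participant(s) in ", source,
            " have best-corrected acuity worse than presenting acuity ",
            "(kept; field data may contain this)")
  }
  d$age <- as.integer(d$age)
  d$.row <- NULL
  attr(d, "rejected") <- rejected
  class(d) <- c("eyecover_survey", class(d))
  d
}

#' Write a participant table to CSV
#'
#' Inverse of [read_survey()]: `read_survey(write_survey(x, f))` recovers
#' `x` field for field.
#'
#' @param survey a participant tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  out <- tibble::as_tibble(survey)[survey_columns]
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read an age-sex population table
#'
#' Reads census counts for the survey area with columns
#' `sex, age_band, count`. Age bands may be the four analysis bands
#' (`50-59, 60-69, 70-79, 80+`) or finer 5-year bands
#' (`50-54, 55-59, ..., 80+` or `80-84, 85+` etc.), which are aggregated
#' upward; totals per sex are conserved by the aggregation. All eight
#' analysis strata (2 sexes x 4 bands) must be present after aggregation.
#'
#' @param path path to the population CSV.
#' @return a tibble with columns `sex`, `age_band`, `count` (8 rows).
#' @export
read_population <- function(path) {
  if (!file.exists(path)) {
    stop("population file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    sex = "c", age_band = "c", count = "d"), progress = FALSE,
    show_col_types = FALSE)
  validate_population(raw, source = path)
}

#' Validate and aggregate a population table
#'
#' @param data data frame with columns `sex`, `age_band`, `count`.
#' @param source label used in messages.
#' @param sexes which sexes must be present (both, for the full 8-stratum
#'   table; a single sex for sex-restricted estimation).
#' @return 8-row tibble at analysis-band resolution (4 rows per requested
#'   sex).
#' @export
validate_population <- function(data, source = "population data",
                                sexes = c("F", "M")) {
  need <- c("sex", "age_band", "count")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("schema error in ", source, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- tibble::as_tibble(data)[need]
  if (any(is.na(d$count) | d$count < 0)) {
    stop("value error in ", source, ": counts must be non-negative",
         call. = FALSE)
  }
  if (any(!d$sex %in% c("F", "M"))) {
    stop("value error in ", source, ": sex must be F or M", call. = FALSE)
  }
  lower <- suppressWarnings(as.integer(sub("[-+].*$", "", d$age_band)))
  if (any(is.na(lower) | lower < 50)) {
    stop("value error in ", source, ": unparseable age band(s) ",
         paste(unique(d$age_band[is.na(lower) | lower < 50]), collapse = ", "),
         call. = FALSE)
  }
  d$age_band <- age_band(lower)
  out <- d |>
    dplyr::group_by(sex = .data$sex, age_band = .data$age_band) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  out <- dplyr::filter(out, .data$sex %in% sexes)
  full <- tidyr::expand_grid(sex = sexes, age_band = age_bands)
  missing_strata <- dplyr::anti_join(full, out, by = c("sex", "age_band"))
  if (nrow(missing_strata) > 0) {
    stop("schema error in ", source, ": missing stratum(s) ",
         paste(missing_strata$sex, missing_strata$age_band,
               collapse = "; "), call. = FALSE)
  }
  if (sum(out$count) <= 0) {
    stop("value error in ", source, ": total population must be positive",
         call. = FALSE)
  }
  dplyr::arrange(out, .data$sex, match(.data$age_band, age_bands))
}

#' Read survey metadata
#'
#' Reads a YAML or JSON metadata file with fields `survey_id`, `country`,
#' `year`, `scope` (`NATIONAL` or `SUBNATIONAL`; a series of subnational
#' surveys designed for national coverage is declared `NATIONAL` here, not
#' inferred), and optional free-text `region_label` and `income_label`.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return a one-row tibble of metadata.
#' @export
read_survey_meta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path,
                               call. = FALSE)
  m <- yaml::read_yaml(path)   # yaml parser also accepts JSON
  validate_survey_meta(m, source = path)
}

#' Validate survey metadata
#' @param meta a named list or one-row data frame of metadata fields.
#' @param source label used in messages.
#' @return a one-row tibble.
#' @export
validate_survey_meta <- function(meta, source = "metadata") {
  m <- as.list(meta)
  for (f in c("survey_id", "country", "year", "scope")) {
    if (is.null(m[[f]])) {
      stop("schema error in ", source, ": missing field ", f, call. = FALSE)
    }
  }
  year <- as.integer(m$year)
  if (is.na(year) || year < 2000 || year > 2035) {
    stop("value error in ", source, ": implausible year ", m$year,
         call. = FALSE)
  }
  scope <- toupper(as.character(m$scope))
  if (!scope %in% c("NATIONAL", "SUBNATIONAL")) {
    stop("value error in ", source,
         ": scope must be NATIONAL or SUBNATIONAL", call. = FALSE)
  }
  tibble::tibble(
    survey_id = as.character(m$survey_id),
    country = as.character(m$country),
    year = year,
    scope = scope,
    region_label = as.character(m$region_label %||% NA_character_),
    income_label = as.character(m$income_label %||% NA_character_)
  )
}

estimate_columns <- c("indicator", "sex", "value", "se", "ci_low", "ci_high",
                      "n_examined", "n_clusters", "num_weighted",
                      "den_weighted", "config")

#' Write an estimates table to CSV
#'
#' Full double precision is written so that
#' `read_estimates(write_estimates(x, f))` equals `x`.
#'
#' @param estimates a tibble of coverage estimates as returned by
#'   [coverage_estimate()] (zero rows allowed; the header is still written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  est <- tibble::as_tibble(estimates)
  missing_cols <- setdiff(estimate_columns, names(est))
  if (length(missing_cols) > 0) {
    stop("estimates table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(est[estimate_columns], path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read an estimates table written by [write_estimates()]
#' @param path path to the estimates CSV.
#' @return a tibble of estimates.
#' @export
read_estimates <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    indicator = "c", sex = "c", value = "d", se = "d", ci_low = "d",
    ci_high = "d", n_examined = "d", n_clusters = "d", num_weighted = "d",
    den_weighted = "d", config = "c"), progress = FALSE,
    show_col_types = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
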