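#' Is an eye operated for cataract?
#'
#' An operated eye is pseudophakic (intraocular lens implant) or aphakic
#' (lens removed, no implant). Any other status — clear lens, unoperated
#' cataract, no view of the lens, or missing — is not operated.
#'
#' @param lens character vector of lens status codes ([lens_levels]).
#' @return logical vector, `FALSE` (never `NA`) for missing status.
#' @export
eye_operated <- function(lens) {
  !is.na(lens) & lens %in% c("PSEUDOPHAKIA", "APHAKIA")
}

#' Does an unoperated eye have operable cataract?
#'
#' An operable eye has an unoperated cataract (`PHAKIC_CATARACT`) with
#' best-corrected acuity strictly worse than the surgical threshold, and —
#' unless `require_cataract_cause = FALSE` — cataract recorded as the
#' principal cause of impairment, so that vision loss from other disease
#' does not create apparent unmet surgical need.
#'
#' @param lens,bcva,cause parallel character vectors: lens status,
#'   best-corrected acuity category, principal cause code.
#' @param surgical_threshold Snellen cut (`"3/60"`, `"6/60"`, `"6/18"`,
#'   `"6/12"`).
#' @param require_cataract_cause require `cause == "CATARACT"`? Default
#'   `TRUE`.
#' @return logical vector, `FALSE` (never `NA`) when any needed field is
#'   missing.
#' @export
eye_operable <- function(lens, bcva, cause, surgical_threshold = "6/18",
                         require_cataract_cause = TRUE) {
  op <- !is.na(lens) & lens == "PHAKIC_CATARACT" &
    va_worse_than(bcva, surgical_threshold)
  if (require_cataract_cause) {
    op <- op & !is.na(cause) & cause == "CATARACT"
  }
  op
}

#' Classify participants into CSC and eCSC numerator/denominator groups
#'
#' The person-level classification behind both coverage indicators.
#' For each participant:
#'
#' * `operated` is `"bilateral"`, `"unilateral"` or `"none"` according to
#'   [eye_operated()] applied to both eyes;
#' * `in_csc_num`: under the `"all_operated"` rule, any person with at
#'   least one operated eye; under `"fellow_impaired_only"`, a unilateral
#'   case qualifies only when the unoperated fellow eye has best-corrected
#'   acuity worse than the surgical threshold (a fellow eye that cannot be
#'   graded excludes the person, tallied in `csc_excluded`);
#' * `in_denom`: persons in the CSC numerator plus unoperated persons with
#'   at least one operable eye ([eye_operable()]);
#' * `postop_pva`: presenting acuity of the better operated eye (for
#'   bilateral surgery the better of the two; for unilateral, the single
#'   operated eye);
#' * `in_ecsc_num`: CSC numerator members whose `postop_pva` is at or
#'   better than the good-outcome threshold. An operated person whose
#'   presenting acuity is missing in every operated eye cannot be assessed
#'   and is excluded from the eCSC numerator, tallied in `ecsc_excluded`.
#'
#' Participants with missing lens status in both eyes cannot be classified
#' at all; they are flagged `unclassifiable` and excluded from every group.
#' Classification is a pure, deterministic function of the input rows.
#'
#' @param survey a participant tibble (see [read_survey()] for the schema).
#' @param cfg an [indicator_config()].
#' @return the input tibble with columns `age_band`, `operated`,
#'   `in_denom`, `in_csc_num`, `in_ecsc_num`, `postop_pva`,
#'   `unclassifiable`, `csc_excluded`, `ecsc_excluded` appended.
#' @examples
#' s <- simulate_raab_survey(raab_scenario(n_clusters = 5,
#'                                         cluster_size = 20), seed = 1)
#' dplyr::count(classify_participants(s$survey, indicator_config()),
#'              operated, in_csc_num, in_ecsc_num)
#' @export
classify_participants <- function(survey, cfg = indicator_config()) {
  stopifnot(inherits(cfg, "indicator_config"))
  d <- tibble::as_tibble(survey)
  r_op <- eye_operated(d$r_lens)
  l_op <- eye_operated(d$l_lens)
  n_op <- r_op + l_op
  unclassifiable <- is.na(d$r_lens) & is.na(d$l_lens)

  operated <- dplyr::case_when(
    unclassifiable ~ NA_character_,
    n_op == 2L ~ "bilateral",
    n_op == 1L ~ "unilateral",
    TRUE ~ "none"
  )

  # presenting acuity of the better operated eye
  rr <- ifelse(r_op, va_rank(d$r_pva), NA_integer_)
  lr <- ifelse(l_op, va_rank(d$l_pva), NA_integer_)
  best <- pmin(rr, lr, na.rm = TRUE)
  best[is.infinite(best)] <- NA_integer_
  postop_pva <- ifelse(n_op > 0 & !is.na(best), va_levels[best],
                       NA_character_)

  # fellow (unoperated) eye impairment for the unilateral rule
  fellow_bcva <- ifelse(r_op, d$l_bcva, d$r_bcva)
  fellow_lens <- ifelse(r_op, d$l_lens, d$r_lens)
  fellow_impaired <- va_worse_than(fellow_bcva, cfg$surgical_threshold)
  fellow_gradable <- !is.na(fellow_bcva) &
    (is.na(fellow_lens) | fellow_lens != "NO_VIEW")

  if (cfg$unilateral_rule == "all_operated") {
    in_csc <- !unclassifiable & n_op >= 1L
    csc_excluded <- rep(FALSE, nrow(d))
  } else {
    in_csc <- !unclassifiable &
      (n_op == 2L | (n_op == 1L & fellow_gradable & fellow_impaired))
    csc_excluded <- !unclassifiable & n_op == 1L & !fellow_gradable
  }

  r_able <- eye_operable(d$r_lens, d$r_bcva, d$r_cause,
                         cfg$surgical_threshold, cfg$require_cataract_cause)
  l_able <- eye_operable(d$l_lens, d$l_bcva, d$l_cause,
                         cfg$surgical_threshold, cfg$require_cataract_cause)
  in_denom <- in_csc | (!unclassifiable & n_op == 0L & (r_able | l_able))

  good <- !is.na(postop_pva) & va_at_least(postop_pva, cfg$outcome_threshold)
  ecsc_excluded <- in_csc & is.na(postop_pva)
  in_ecsc <- in_csc & good

  d$age_band <- age_band(d$age)
  d$operated <- operated
  d$in_denom <- in_denom
  d$in_csc_num <- in_csc
  d$in_ecsc_num <- in_ecsc
  d$postop_pva <- postop_pva
  d$unclassifiable <- unclassifiable
  d$csc_excluded <- csc_excluded
  d$ecsc_excluded <- ecsc_excluded
  d
}

#' Tally indicator counts by age-sex stratum and by cluster
#'
#' Applies [classify_participants()] and sums the person-level flags.
#' Counts are additive over participants, so the stratum totals and the
#' cluster totals both equal the survey totals.
#'
#' @inheritParams classify_participants
#' @param by `"stratum"` (sex x age band), `"cluster"`, or `"total"`.
#' @return a tibble with grouping columns and counts `examined`, `denom`,
#'   `csc_num`, `ecsc_num`, `unclassifiable`, `csc_excluded`,
#'   `ecsc_excluded`.
#' @export
survey_counts <- function(survey, cfg = indicator_config(),
                          by = c("stratum", "cluster", "total")) {
  by <- match.arg(by)
  cl <- classify_participants(survey, cfg)
  keys <- switch(by,
    stratum = c("sex", "age_band"),
    cluster = "cluster_id",
    total = character(0)
  )
  cl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      examined = dplyr::n(),
      denom = sum(.data$in_denom),
      csc_num = sum(.data$in_csc_num),
      ecsc_num = sum(.data$in_ecsc_num),
      unclassifiable = sum(.data$unclassifiable),
      csc_excluded = sum(.data$csc_excluded),
      ecsc_excluded = sum(.data$ecsc_excluded),
      .groups = "drop"
    )
}
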