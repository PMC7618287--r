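#' Visual acuity categories and threshold comparisons
#'
#' RAAB-style surveys record visual acuity on a five-level ordinal scale
#' rather than as a continuous measure. The levels, from best to worst, are:
#'
#' * `GE_6_12` — can see 6/12 or better
#' * `LT_6_12_GE_6_18` — worse than 6/12 but 6/18 or better
#' * `LT_6_18_GE_6_60` — worse than 6/18 but 6/60 or better
#' * `LT_6_60_GE_3_60` — worse than 6/60 but 3/60 or better
#' * `LT_3_60` — worse than 3/60 (blind range)
#'
#' Every threshold used by the coverage indicators is a cut-point of this
#' scale, expressed either as "worse than X" (the cataract surgical
#' threshold, deciding whether an unoperated cataract eye counts as needing
#' surgery) or "X or better" (the good-outcome threshold an operated eye
#' must reach). Missing values satisfy neither direction of comparison.
#'
#' @name va-scale
#' @keywords internal
NULL

#' Ordered visual acuity category codes, best first.
#' @export
va_levels <- c("GE_6_12", "LT_6_12_GE_6_18", "LT_6_18_GE_6_60",
               "LT_6_60_GE_3_60", "LT_3_60")

#' Lens status codes recognised in survey data.
#' @export
lens_levels <- c("PHAKIC_CLEAR", "PHAKIC_CATARACT", "PSEUDOPHAKIA",
                 "APHAKIA", "NO_VIEW")

#' Cause-of-vision-impairment codes recognised in survey data.
#' @export
cause_levels <- c("CATARACT", "OTHER", "NONE")

# Snellen cut-points usable as thresholds, mapped to the rank of the best
# category that is already "worse than" the cut (see va_rank below).
.va_cuts <- c("6/12" = 1L, "6/18" = 2L, "6/60" = 3L, "3/60" = 4L)

#' Numeric rank of a visual acuity category
#'
#' Returns 1 for the best category (`GE_6_12`) through 5 for the worst
#' (`LT_3_60`); `NA` input gives `NA`.
#'
#' @param va character vector of visual acuity category codes.
#' @return integer vector of ranks.
#' @export
va_rank <- function(va) {
  r <- match(va, va_levels)
  bad <- !is.na(va) & is.na(r)
  if (any(bad)) {
    stop("unknown visual acuity code(s): ",
         paste(unique(va[bad]), collapse = ", "), call. = FALSE)
  }
  r
}

.check_cut <- function(cut, allowed = names(.va_cuts)) {
  if (length(cut) != 1L || !cut %in% allowed) {
    stop("threshold must be one of ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  cut
}

#' Is visual acuity strictly worse than a Snellen cut?
#'
#' @param va character vector of visual acuity category codes.
#' @param cut one of `"3/60"`, `"6/60"`, `"6/18"`, `"6/12"`.
#' @return logical vector; `FALSE` (never `NA`) for missing acuity.
#' @examples
#' va_worse_than(c("LT_6_18_GE_6_60", "GE_6_12", NA), "6/18")
#' @export
va_worse_than <- function(va, cut) {
  .check_cut(cut)
  r <- va_rank(va)
  !is.na(r) & r > .va_cuts[[cut]]
}

#' Is visual acuity at or better than a Snellen cut?
#'
#' @inheritParams va_worse_than
#' @param cut one of `"6/18"`, `"6/12"` (the good-outcome cuts).
#' @return logical vector; `FALSE` (never `NA`) for missing acuity.
#' @export
va_at_least <- function(va, cut) {
  .check_cut(cut, c("6/18", "6/12"))
  r <- va_rank(va)
  !is.na(r) & r <= .va_cuts[[cut]]
}

#' Indicator configuration for CSC and eCSC
#'
#' Bundles the three choices that define the coverage indicators:
#' the cataract surgical threshold (an unoperated cataract eye with
#' best-corrected acuity strictly worse than this cut counts as needing
#' surgery), the good-outcome threshold (an operated person whose better
#' operated eye presents at or better than this cut counts as effectively
#' covered), and the rule for people with only one operated eye.
#'
#' Under `unilateral_rule = "all_operated"` (default) every person with at
#' least one operated eye enters the CSC numerator. Under
#' `"fellow_impaired_only"` a person with exactly one operated eye counts
#' only when the unoperated fellow eye has best-corrected acuity worse than
#' the surgical threshold; unilateral cases whose fellow eye cannot be
#' graded (no view or missing) are excluded from the numerator and counted
#' in the exclusion tally.
#'
#' @param surgical_threshold Snellen cut, one of `"3/60"`, `"6/60"`,
#'   `"6/18"`, `"6/12"`. Default `"6/18"`.
#' @param outcome_threshold Snellen cut, `"6/18"` or `"6/12"`. Default
#'   `"6/18"`.
#' @param unilateral_rule `"all_operated"` or `"fellow_impaired_only"`.
#' @param require_cataract_cause should an operable eye also have cataract
#'   recorded as the principal cause of impairment? Default `TRUE`, so
#'   vision loss attributed to other causes does not enter the denominator.
#' @return an object of class `indicator_config`.
#' @examples
#' indicator_config()
#' indicator_config("6/12", "6/12", "fellow_impaired_only")
#' @export
indicator_config <- function(surgical_threshold = "6/18",
                             outcome_threshold = "6/18",
                             unilateral_rule = c("all_operated",
                                                 "fellow_impaired_only"),
                             require_cataract_cause = TRUE) {
  .check_cut(surgical_threshold)
  .check_cut(outcome_threshold, c("6/18", "6/12"))
  unilateral_rule <- match.arg(unilateral_rule)
  stopifnot(is.logical(require_cataract_cause),
            length(require_cataract_cause) == 1L)
  structure(
    list(surgical_threshold = surgical_threshold,
         outcome_threshold = outcome_threshold,
         unilateral_rule = unilateral_rule,
         require_cataract_cause = require_cataract_cause),
    class = "indicator_config"
  )
}

#' Canonical one-line descriptor of an indicator configuration
#'
#' Written into every estimate row so outputs are self-describing.
#'
#' @param cfg an [indicator_config()].
#' @return a string like `"st<6/18|ot>=6/18|ALL_OPERATED"`.
#' @export
config_label <- function(cfg) {
  stopifnot(inherits(cfg, "indicator_config"))
  paste0("st<", cfg$surgical_threshold,
         "|ot>=", cfg$outcome_threshold,
         "|", toupper(cfg$unilateral_rule),
         if (!cfg$require_cataract_cause) "|ANY_CAUSE" else "")
}

#' @export
print.indicator_config <- function(x, ...) {
  cat("<indicator_config> ", config_label(x), "\n", sep = "")
  invisible(x)
}

#' Age bands used for post-stratification
#'
#' Maps age in years (>= 50) to the four analysis bands `50-59`, `60-69`,
#' `70-79`, `80+`. Bands are left-closed: age 50 belongs to `50-59`,
#' age 80 to `80+`.
#'
#' @param age integer vector of ages in years.
#' @return character vector of band labels.
#' @examples
#' age_band(c(50, 59, 60, 80, 97))
#' @export
age_band <- function(age) {
  stopifnot(is.numeric(age))
  if (any(!is.na(age) & age < 50)) {
    stop("age_band() is defined for ages >= 50 only", call. = FALSE)
  }
  cut(age, breaks = c(50, 60, 70, 80, Inf), right = FALSE,
      labels = age_bands) |> as.character()
}

#' Analysis age-band labels, youngest first.
#' @export
age_bands <- c("50-59", "60-69", "70-79", "80+")
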