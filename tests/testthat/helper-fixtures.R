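# Build participant rows succinctly: defaults are a healthy 62-year-old
# woman with clear lenses and full acuity in both eyes.
participant <- function(id = "p1", cluster = "c1", age = 62, sex = "F",
                        r_lens = "PHAKIC_CLEAR", l_lens = "PHAKIC_CLEAR",
                        r_pva = "GE_6_12", l_pva = "GE_6_12",
                        r_bcva = "GE_6_12", l_bcva = "GE_6_12",
                        r_cause = "NONE", l_cause = "NONE") {
  tibble::tibble(participant_id = id, cluster_id = cluster,
                 age = as.integer(age), sex = sex,
                 r_lens = r_lens, l_lens = l_lens,
                 r_pva = r_pva, l_pva = l_pva,
                 r_bcva = r_bcva, l_bcva = l_bcva,
                 r_cause = r_cause, l_cause = l_cause)
}

# Uniform population table: the same count in each of the 8 strata.
flat_population <- function(count = 100) {
  tidyr::expand_grid(sex = c("F", "M"),
                     age_band = c("50-59", "60-69", "70-79", "80+")) |>
    dplyr::mutate(count = count)
}

# Population table equal to the sample's own stratum counts times `mult`
# (uniform sampling fraction 1/mult across all strata).
proportional_population <- function(survey, mult = 100) {
  tidyr::expand_grid(sex = c("F", "M"),
                     age_band = c("50-59", "60-69", "70-79", "80+")) |>
    dplyr::left_join(
      dplyr::count(dplyr::mutate(tibble::as_tibble(survey),
                                 age_band = age_band(age)),
                   sex, age_band),
      by = c("sex", "age_band")) |>
    dplyr::mutate(count = dplyr::coalesce(n, 0L) * mult, n = NULL)
}

# Random participants over the full code space (including missing values)
# for property-style tests of the classification rules.
random_participants <- function(n, seed) {
  set.seed(seed)
  draw <- function(levels, p_na = 0.1) {
    x <- sample(levels, n, replace = TRUE)
    x[stats::runif(n) < p_na] <- NA_character_
    x
  }
  tibble::tibble(
    participant_id = sprintf("r%05d", seq_len(n)),
    cluster_id = sample(sprintf("c%02d", 1:20), n, replace = TRUE),
    age = sample(50:95, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    r_lens = draw(lens_levels), l_lens = draw(lens_levels),
    r_pva = draw(va_levels), l_pva = draw(va_levels),
    r_bcva = draw(va_levels), l_bcva = draw(va_levels),
    r_cause = draw(cause_levels), l_cause = draw(cause_levels)
  )
}

all_indicator_configs <- function(unilateral_rule = "all_operated") {
  cfgs <- tidyr::expand_grid(st = c("3/60", "6/60", "6/18", "6/12"),
                             ot = c("6/18", "6/12"))
  purrr::pmap(cfgs, function(st, ot) {
    indicator_config(st, ot, unilateral_rule)
  })
}

# Small, quick scenario for tests that only need a valid survey.
small_scenario <- function(...) {
  raab_scenario(stratum_population = rep(300, 8),
                n_clusters = 8, cluster_size = 40, n_pop_clusters = 20,
                ...)
}
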