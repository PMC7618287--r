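#' Scenario configuration for synthetic RAAB-style surveys
#'
#' Defines a synthetic source population of adults aged 50+ and a
#' two-stage cluster survey of it, with every probability that drives the
#' coverage indicators directly configurable so that edge-case fixtures
#' are one configuration away. The person model is intentionally minimal:
#' persons are independent apart from a cluster-level random effect on
#' access to surgery, and there is no disease progression — just the
#' cross-sectional states the indicators read.
#'
#' Per person, in order:
#'
#' 1. With the age-band probability `p_cataract` the person developed
#'    cataract needing surgery; with probability `unilateral_fraction`
#'    that need is unilateral (one eye), otherwise bilateral.
#' 2. A person with need is operated with probability
#'    `plogis(qlogis(p_access) + sex_log_odds * male +
#'    age_log_odds * (band - 1) + b_cluster)`, where `b_cluster` is a
#'    normal cluster effect whose variance is set from `rho_access` (the
#'    latent-logistic intra-cluster correlation,
#'    `sigma^2 = rho * pi^2/3 / (1 - rho)`). An operated person with
#'    bilateral need has both eyes operated with probability
#'    `p_both_eyes`, else one; operated eyes are aphakic (no implant)
#'    with probability `p_aphakia`, else pseudophakic.
#' 3. Each operated eye presents well (acuity 6/18 or better) with
#'    probability `p_good_outcome`; the exact category is drawn from
#'    `good_pva_probs` (over 6/12-or-better and 6/12-to-6/18) or
#'    `poor_pva_probs` (over the three categories below 6/18).
#' 4. Unoperated cataract eyes draw best-corrected acuity from
#'    `cataract_bcva_probs` over the four categories below 6/12, with
#'    presenting acuity equal to best-corrected (cataract is not
#'    refractive); cause is cataract.
#' 5. With probability `p_other_impairment` an otherwise healthy person
#'    has one eye impaired by a non-cataract cause (`OTHER`), which must
#'    not create apparent surgical need.
#'
#' Defaults mirror the scale of real RAAB surveys: about 3000 participants
#' in 50 clusters of 60, drawn from a source population of 48,000 in 120
#' population clusters, with moderate access (50%), a male advantage in
#' access, an age gradient in cataract, and 75% good outcomes. Cluster
#' sizes and intra-cluster correlations of real surveys are not published;
#' these defaults are plausible placeholders.
#'
#' @param stratum_population named or ordered numeric vector of population
#'   counts for the 8 strata (F then M, youngest band first), or `NULL`
#'   for the default 48,000-person pyramid.
#' @param p_cataract length-4 probability of cataract need per age band.
#' @param unilateral_fraction share of need that is unilateral.
#' @param p_access baseline probability of surgery given need (female,
#'   50-59, average cluster).
#' @param sex_log_odds male log-odds offset on access.
#' @param age_log_odds per-band log-odds gradient on access.
#' @param rho_access latent intra-cluster correlation of access, in
#'   `[0, 0.3]`.
#' @param p_both_eyes probability both eyes are operated when bilateral
#'   need is operated.
#' @param p_aphakia probability an operated eye is aphakic.
#' @param p_good_outcome probability an operated eye presents at 6/18 or
#'   better.
#' @param good_pva_probs,poor_pva_probs,cataract_bcva_probs category
#'   distributions described above (each sums to 1).
#' @param p_other_impairment probability of non-cataract impairment in an
#'   otherwise healthy person.
#' @param n_clusters,cluster_size stage-1 and stage-2 sample sizes.
#' @param n_pop_clusters number of clusters the population is partitioned
#'   into.
#' @return an object of class `raab_scenario` (a validated list).
#' @export
raab_scenario <- function(stratum_population = NULL,
                          p_cataract = c(0.05, 0.12, 0.22, 0.35),
                          unilateral_fraction = 0.3,
                          p_access = 0.5,
                          sex_log_odds = 0.3,
                          age_log_odds = 0.1,
                          rho_access = 0.05,
                          p_both_eyes = 0.5,
                          p_aphakia = 0.05,
                          p_good_outcome = 0.75,
                          good_pva_probs = c(0.75, 0.25),
                          poor_pva_probs = c(0.5, 0.3, 0.2),
                          cataract_bcva_probs = c(0.15, 0.40, 0.25, 0.20),
                          p_other_impairment = 0.05,
                          n_clusters = 50,
                          cluster_size = 60,
                          n_pop_clusters = 120) {
  if (is.null(stratum_population)) {
    shares <- c(0.42, 0.30, 0.19, 0.09)
    stratum_population <- round(48000 * c(0.52 * shares, 0.48 * shares))
  }
  stopifnot(length(stratum_population) == 8,
            all(stratum_population >= 0), sum(stratum_population) > 0,
            length(p_cataract) == 4)
  probs <- c(p_cataract, unilateral_fraction, p_access, p_both_eyes,
             p_aphakia, p_good_outcome, good_pva_probs, poor_pva_probs,
             cataract_bcva_probs, p_other_impairment)
  stopifnot(all(probs >= 0 & probs <= 1),
            abs(sum(good_pva_probs) - 1) < 1e-9,
            abs(sum(poor_pva_probs) - 1) < 1e-9,
            abs(sum(cataract_bcva_probs) - 1) < 1e-9,
            rho_access >= 0, rho_access <= 0.3,
            n_clusters >= 2, cluster_size >= 1, n_pop_clusters >= n_clusters)
  structure(
    list(stratum_population = as.numeric(stratum_population),
         p_cataract = p_cataract,
         unilateral_fraction = unilateral_fraction,
         p_access = p_access, sex_log_odds = sex_log_odds,
         age_log_odds = age_log_odds, rho_access = rho_access,
         p_both_eyes = p_both_eyes, p_aphakia = p_aphakia,
         p_good_outcome = p_good_outcome,
         good_pva_probs = good_pva_probs,
         poor_pva_probs = poor_pva_probs,
         cataract_bcva_probs = cataract_bcva_probs,
         p_other_impairment = p_other_impairment,
         n_clusters = as.integer(n_clusters),
         cluster_size = as.integer(cluster_size),
         n_pop_clusters = as.integer(n_pop_clusters)),
    class = "raab_scenario"
  )
}

# draw one VA category per row of `idx` from a probability vector over
# the given category codes
.draw_va <- function(n, probs, codes) {
  codes[1L + findInterval(stats::runif(n), cumsum(probs)[-length(probs)],
                          left.open = FALSE)]
}

#' Generate a synthetic source population with known truth
#'
#' Draws the full person roster of a [raab_scenario()]: one row per person
#' in the canonical survey schema, pre-partitioned into population
#' clusters with cluster random effects on access. Deterministic under a
#' fixed seed. The exact census values of the coverage indicators for this
#' roster are available through [roster_truth()].
#'
#' @param scenario a [raab_scenario()].
#' @param seed integer seed for the draw.
#' @return a list with elements `roster` (participant tibble, one row per
#'   person in the population), `population` (8-row stratum count table),
#'   and `scenario`.
#' @export
generate_population <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "raab_scenario"))
  set.seed(seed)
  sc <- scenario
  strata <- tidyr::expand_grid(sex = c("F", "M"), age_band = age_bands)
  strata$n <- sc$stratum_population
  n <- sum(strata$n)

  sex <- rep(strata$sex, strata$n)
  band <- rep(strata$age_band, strata$n)
  band_i <- match(band, age_bands)
  age_lo <- c(50L, 60L, 70L, 80L)[band_i]
  age_span <- c(10L, 10L, 10L, 15L)[band_i]
  age <- age_lo + floor(stats::runif(n) * age_span)

  cluster <- sample(rep_len(seq_len(sc$n_pop_clusters), n))
  sigma <- if (sc$rho_access > 0) {
    sqrt(sc$rho_access * pi^2 / 3 / (1 - sc$rho_access))
  } else 0
  b_cluster <- stats::rnorm(sc$n_pop_clusters, 0, sigma)[cluster]

  need <- stats::runif(n) < sc$p_cataract[band_i]
  uni_need <- need & stats::runif(n) < sc$unilateral_fraction
  eta <- stats::qlogis(sc$p_access) +
    sc$sex_log_odds * (sex == "M") +
    sc$age_log_odds * (band_i - 1) + b_cluster
  operated <- need & stats::runif(n) < stats::plogis(eta)
  both_operated <- operated & !uni_need & stats::runif(n) < sc$p_both_eyes

  # eye-slot layout: slot A carries the (first) affected/operated eye,
  # slot B the fellow eye; slots are randomly assigned to right/left
  op_A <- operated
  op_B <- both_operated
  cat_A <- need & !operated                       # unoperated cataract
  cat_B <- need & !uni_need & !operated
  # unilateral operated with bilateral need keep cataract in fellow eye
  cat_B <- cat_B | (operated & !uni_need & !both_operated)

  other <- !need & stats::runif(n) < sc$p_other_impairment

  draw_eye <- function(op, cat, oth) {
    lens <- rep("PHAKIC_CLEAR", n)
    pva <- rep("GE_6_12", n)
    bcva <- rep("GE_6_12", n)
    cause <- rep("NONE", n)

    n_op <- sum(op)
    if (n_op > 0) {
      lens[op] <- ifelse(stats::runif(n_op) < sc$p_aphakia,
                         "APHAKIA", "PSEUDOPHAKIA")
      good <- stats::runif(n_op) < sc$p_good_outcome
      v <- character(n_op)
      v[good] <- .draw_va(sum(good), sc$good_pva_probs, va_levels[1:2])
      v[!good] <- .draw_va(sum(!good), sc$poor_pva_probs, va_levels[3:5])
      pva[op] <- v
      bcva[op] <- v
      cause[op] <- "NONE"
    }
    n_cat <- sum(cat)
    if (n_cat > 0) {
      lens[cat] <- "PHAKIC_CATARACT"
      v <- .draw_va(n_cat, sc$cataract_bcva_probs, va_levels[2:5])
      pva[cat] <- v
      bcva[cat] <- v
      cause[cat] <- "CATARACT"
    }
    n_oth <- sum(oth)
    if (n_oth > 0) {
      v <- .draw_va(n_oth, c(0.4, 0.3, 0.2, 0.1), va_levels[2:5])
      pva[oth] <- v
      bcva[oth] <- v
      cause[oth] <- "OTHER"
    }
    list(lens = lens, pva = pva, bcva = bcva, cause = cause)
  }

  eye_A <- draw_eye(op_A, cat_A, other)
  eye_B <- draw_eye(op_B, cat_B, rep(FALSE, n))
  a_is_right <- stats::runif(n) < 0.5
  pick <- function(field, right) {
    ifelse(a_is_right == right, eye_A[[field]], eye_B[[field]])
  }
  roster <- tibble::tibble(
    participant_id = sprintf("p%07d", seq_len(n)),
    cluster_id = sprintf("c%03d", cluster),
    age = as.integer(age),
    sex = sex,
    r_lens = pick("lens", TRUE), l_lens = pick("lens", FALSE),
    r_pva = pick("pva", TRUE), l_pva = pick("pva", FALSE),
    r_bcva = pick("bcva", TRUE), l_bcva = pick("bcva", FALSE),
    r_cause = pick("cause", TRUE), l_cause = pick("cause", FALSE)
  )
  pop_table <- dplyr::rename(strata, count = "n")
  list(roster = roster, population = pop_table, scenario = scenario)
}

#' Exact census truth of the coverage indicators for a roster
#'
#' Brute-force ground truth: applies [classify_participants()] to every
#' person in the population and reads off the census CSC, eCSC, relative
#' quality gap, and male-female risk difference and risk ratio in eCSC.
#' No sampling and no weighting is involved (on a census both are inert),
#' so these are the exact values an unbiased estimator targets.
#'
#' @param roster a full-population participant tibble
#'   ([generate_population()]).
#' @param cfg an [indicator_config()].
#' @return a one-row tibble: `csc`, `ecsc`, `quality_gap`, `sex_rd`,
#'   `sex_rr` (all on the percent scale except the ratio).
#' @export
roster_truth <- function(roster, cfg = indicator_config()) {
  cl <- classify_participants(roster, cfg)
  rate <- function(d) {
    den <- sum(d$in_denom)
    c(csc = if (den > 0) 100 * sum(d$in_csc_num) / den else NA_real_,
      ecsc = if (den > 0) 100 * sum(d$in_ecsc_num) / den else NA_real_)
  }
  all_r <- rate(cl)
  m <- rate(dplyr::filter(cl, .data$sex == "M"))
  f <- rate(dplyr::filter(cl, .data$sex == "F"))
  tibble::tibble(
    csc = all_r[["csc"]], ecsc = all_r[["ecsc"]],
    quality_gap = quality_gap(all_r[["csc"]], all_r[["ecsc"]]),
    sex_rd = m[["ecsc"]] - f[["ecsc"]],
    sex_rr = if (!is.na(f[["ecsc"]]) && f[["ecsc"]] > 0)
      m[["ecsc"]] / f[["ecsc"]] else NA_real_
  )
}

#' Draw a two-stage cluster survey from a synthetic population
#'
#' Stage 1 samples `n_clusters` population clusters without replacement;
#' stage 2 samples `cluster_size` persons without replacement within each
#' sampled cluster. Returns the survey together with the stratum
#' population table of the full roster (the post-stratification target).
#' Deterministic under a fixed seed.
#'
#' @param pop a population as returned by [generate_population()].
#' @param seed integer seed for the sampling draw.
#' @param n_clusters,cluster_size override the scenario's sample design.
#' @return a list with elements `survey` (participant tibble) and
#'   `population` (8-row stratum table).
#' @export
sample_survey <- function(pop, seed = 1L,
                          n_clusters = pop$scenario$n_clusters,
                          cluster_size = pop$scenario$cluster_size) {
  roster <- pop$roster
  set.seed(seed)
  all_clusters <- unique(roster$cluster_id)
  if (n_clusters > length(all_clusters)) {
    stop("cannot sample ", n_clusters, " clusters from a population of ",
         length(all_clusters), call. = FALSE)
  }
  chosen <- sample(all_clusters, n_clusters)
  idx <- split(seq_len(nrow(roster)), roster$cluster_id)
  rows <- unlist(lapply(chosen, function(cl) {
    in_cl <- idx[[cl]]
    if (length(in_cl) < cluster_size) {
      stop("cluster ", cl, " has only ", length(in_cl),
           " persons; cannot sample ", cluster_size, call. = FALSE)
    }
    sample(in_cl, cluster_size)
  }), use.names = FALSE)
  list(survey = roster[rows, ], population = pop$population)
}

#' Simulate one RAAB-style survey end to end
#'
#' Convenience wrapper: [generate_population()] with `seed`, then
#' [sample_survey()] with `seed + 1`, plus the census truth at `cfg`.
#'
#' @param scenario a [raab_scenario()].
#' @param seed integer root seed; the population draw uses `seed` and the
#'   sampling stage `seed + 1`, so each stage is independently
#'   reproducible.
#' @param cfg an [indicator_config()] used for the reported truth.
#' @return a list with `survey`, `population`, `truth`
#'   ([roster_truth()] row) and `scenario`.
#' @export
simulate_raab_survey <- function(scenario = raab_scenario(), seed = 1L,
                                 cfg = indicator_config()) {
  pop <- generate_population(scenario, seed = seed)
  smp <- sample_survey(pop, seed = seed + 1L)
  list(survey = smp$survey, population = smp$population,
       truth = roster_truth(pop$roster, cfg), scenario = scenario)
}
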