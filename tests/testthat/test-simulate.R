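test_that("scenario validation catches impossible configurations", {
  expect_error(raab_scenario(p_access = 1.2), "probs")
  expect_error(raab_scenario(rho_access = 0.5), "rho")
  expect_error(raab_scenario(n_clusters = 1), "n_clusters")
  expect_error(raab_scenario(stratum_population = rep(10, 7)),
               "stratum_population")
  expect_s3_class(raab_scenario(), "raab_scenario")
})

test_that("saturated access and outcomes give CSC = eCSC = 100%", {
  sc <- small_scenario(p_access = 1, p_good_outcome = 1,
                       good_pva_probs = c(1, 0), p_other_impairment = 0)
  pop <- generate_population(sc, seed = 2)
  truth <- roster_truth(pop$roster)
  expect_equal(truth$csc, 100)
  expect_equal(truth$ecsc, 100)
  expect_equal(truth$quality_gap, 0)
})

test_that("no access gives zero coverage", {
  sc <- small_scenario(p_access = 0)
  pop <- generate_population(sc, seed = 2)
  truth <- roster_truth(pop$roster)
  expect_equal(truth$csc, 0)
  expect_equal(truth$ecsc, 0)
})

test_that("roster rates concentrate on the configured probabilities", {
  # bilateral-need-only scenario: every person with need is in the
  # denominator, is covered with probability p_access, and an operated
  # person has a good better-eye outcome with probability p_good when
  # exactly one eye is operated
  sc <- raab_scenario(stratum_population = rep(25000, 8),
                      p_cataract = rep(0.2, 4), unilateral_fraction = 0,
                      p_access = 0.5, sex_log_odds = 0, age_log_odds = 0,
                      rho_access = 0, p_both_eyes = 0,
                      p_good_outcome = 0.8, p_other_impairment = 0,
                      cataract_bcva_probs = c(0, 0.5, 0.3, 0.2),
                      n_clusters = 10, cluster_size = 50,
                      n_pop_clusters = 100)
  pop <- generate_population(sc, seed = 8)
  truth <- roster_truth(pop$roster)
  # 200,000 persons, ~40,000 in the denominator: binomial concentration
  expect_lt(abs(truth$csc - 50), 1)
  expect_lt(abs(truth$ecsc - 40), 1)
  expect_lt(abs(truth$quality_gap - 20), 2)
})

test_that("truth is definitionally consistent and permutation-invariant", {
  sc <- small_scenario()
  pop <- generate_population(sc, seed = 12)
  truth <- roster_truth(pop$roster)
  expect_lte(truth$ecsc, truth$csc)
  expect_equal(truth$quality_gap, quality_gap(truth$csc, truth$ecsc))
  set.seed(1)
  shuffled <- pop$roster[sample(nrow(pop$roster)), ]
  expect_equal(roster_truth(shuffled), truth)
})

test_that("generation and sampling are deterministic under a fixed seed", {
  sc <- small_scenario()
  p1 <- generate_population(sc, seed = 44)
  p2 <- generate_population(sc, seed = 44)
  expect_identical(p1$roster, p2$roster)
  s1 <- sample_survey(p1, seed = 45)
  s2 <- sample_survey(p2, seed = 45)
  expect_identical(s1$survey, s2$survey)
  # and byte-identical on disk
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_survey(s1$survey, f1)
  write_survey(s2$survey, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("emitted population table matches the roster strata exactly", {
  sc <- small_scenario()
  pop <- generate_population(sc, seed = 3)
  smp <- sample_survey(pop, seed = 4)
  expect_equal(sum(smp$population$count), nrow(pop$roster))
  counts <- dplyr::count(
    dplyr::mutate(pop$roster, age_band = age_band(age)), sex, age_band)
  joined <- dplyr::left_join(smp$population, counts,
                             by = c("sex", "age_band"))
  expect_equal(joined$count, as.numeric(joined$n))
  # sample sizes honour the two-stage design
  expect_equal(nrow(smp$survey), sc$n_clusters * sc$cluster_size)
  expect_equal(dplyr::n_distinct(smp$survey$cluster_id), sc$n_clusters)
})

test_that("infeasible sampling designs error", {
  sc <- small_scenario()
  pop <- generate_population(sc, seed = 5)
  expect_error(sample_survey(pop, seed = 1, n_clusters = 999),
               "cannot sample")
  expect_error(sample_survey(pop, seed = 1, cluster_size = 10000),
               "cannot sample")
})

test_that("with rho = 0, cluster coverage dispersion is binomial-like", {
  # compare the between-cluster dispersion statistic of operated status
  # among persons with need against its chi-square expectation
  sc <- raab_scenario(stratum_population = rep(6000, 8),
                      p_cataract = rep(0.3, 4), unilateral_fraction = 0,
                      p_access = 0.5, sex_log_odds = 0, age_log_odds = 0,
                      rho_access = 0, p_other_impairment = 0,
                      n_clusters = 40, cluster_size = 60,
                      n_pop_clusters = 96)
  pop <- generate_population(sc, seed = 19)
  cl <- classify_participants(pop$roster)
  need <- dplyr::filter(cl, in_denom)
  tab <- dplyr::summarise(dplyr::group_by(need, cluster_id),
                          n = dplyr::n(), y = sum(in_csc_num),
                          .groups = "drop")
  p_hat <- sum(tab$y) / sum(tab$n)
  x2 <- sum((tab$y - tab$n * p_hat)^2 / (tab$n * p_hat * (1 - p_hat)))
  df <- nrow(tab) - 1
  # under the null the statistic is ~ chi-square(df)
  expect_gt(x2, stats::qchisq(0.001, df))
  expect_lt(x2, stats::qchisq(0.999, df))

  # and with strong clustering the same statistic blows up
  sc_rho <- raab_scenario(stratum_population = rep(6000, 8),
                          p_cataract = rep(0.3, 4),
                          unilateral_fraction = 0, p_access = 0.5,
                          sex_log_odds = 0, age_log_odds = 0,
                          rho_access = 0.25, p_other_impairment = 0,
                          n_clusters = 40, cluster_size = 60,
                          n_pop_clusters = 96)
  pop_rho <- generate_population(sc_rho, seed = 19)
  cl_rho <- classify_participants(pop_rho$roster)
  need_rho <- dplyr::filter(cl_rho, in_denom)
  tab_rho <- dplyr::summarise(dplyr::group_by(need_rho, cluster_id),
                              n = dplyr::n(), y = sum(in_csc_num),
                              .groups = "drop")
  p_rho <- sum(tab_rho$y) / sum(tab_rho$n)
  x2_rho <- sum((tab_rho$y - tab_rho$n * p_rho)^2 /
                  (tab_rho$n * p_rho * (1 - p_rho)))
  expect_gt(x2_rho, stats::qchisq(0.999, nrow(tab_rho) - 1))
})

test_that("configured sex gap in access shows up in the roster truth", {
  sc <- raab_scenario(stratum_population = rep(20000, 8),
                      p_cataract = rep(0.2, 4), unilateral_fraction = 0,
                      p_access = 0.45, sex_log_odds = 0.4,
                      age_log_odds = 0, rho_access = 0, p_both_eyes = 0,
                      p_good_outcome = 0.8, p_other_impairment = 0,
                      n_clusters = 10, cluster_size = 50,
                      n_pop_clusters = 80)
  pop <- generate_population(sc, seed = 6)
  truth <- roster_truth(pop$roster)
  expected_rd <- (stats::plogis(stats::qlogis(0.45) + 0.4) - 0.45) * 0.8 * 100
  expect_lt(abs(truth$sex_rd - expected_rd), 1.5)
  expect_gt(truth$sex_rr, 1)
})
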