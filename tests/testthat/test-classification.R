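# A 12-person fixture covering every classification branch. The expected
# groups were enumerated by hand from the indicator definitions before
# being frozen here (see each row's comment).
fixture12 <- function() {
  dplyr::bind_rows(
    # 1: bilateral pseudophakia, better-eye pva 6/12+ -> eCSC member
    participant("f01", "c1", r_lens = "PSEUDOPHAKIA", l_lens = "PSEUDOPHAKIA",
                r_pva = "GE_6_12", l_pva = "LT_6_18_GE_6_60"),
    # 2: healthy -> outside denominator
    participant("f02", "c1"),
    # 3: bilateral operable cataract -> denominator only
    participant("f03", "c1", r_lens = "PHAKIC_CATARACT",
                l_lens = "PHAKIC_CATARACT",
                r_pva = "LT_6_60_GE_3_60", l_pva = "LT_6_60_GE_3_60",
                r_bcva = "LT_6_60_GE_3_60", l_bcva = "LT_6_60_GE_3_60",
                r_cause = "CATARACT", l_cause = "CATARACT"),
    # 4: unilateral aphakia with blind operated eye, healthy fellow eye
    participant("f04", "c1", r_lens = "APHAKIA", r_pva = "LT_3_60",
                r_bcva = "LT_3_60"),
    # 5: cataract too mild for the 6/18 surgical cut -> outside denominator
    participant("f05", "c1", r_lens = "PHAKIC_CATARACT",
                r_pva = "LT_6_12_GE_6_18", r_bcva = "LT_6_12_GE_6_18",
                r_cause = "CATARACT"),
    # 6: blind cataract eye but impairment attributed elsewhere -> outside
    participant("f06", "c2", r_lens = "PHAKIC_CATARACT", r_pva = "LT_3_60",
                r_bcva = "LT_3_60", r_cause = "OTHER"),
    # 7: unilateral pseudophakia (good outcome), operable fellow eye
    participant("f07", "c2", r_lens = "PSEUDOPHAKIA",
                r_pva = "LT_6_12_GE_6_18",
                l_lens = "PHAKIC_CATARACT", l_pva = "LT_6_18_GE_6_60",
                l_bcva = "LT_6_18_GE_6_60", l_cause = "CATARACT"),
    # 8: no view of either lens status -> unclassifiable
    participant("f08", "c2", r_lens = NA, l_lens = NA,
                r_pva = NA, l_pva = NA, r_bcva = NA, l_bcva = NA,
                r_cause = NA, l_cause = NA),
    # 9: operated but postoperative acuity missing -> eCSC-excluded
    participant("f09", "c2", r_lens = "PSEUDOPHAKIA", r_pva = NA,
                r_bcva = NA),
    # 10: one NO_VIEW eye, one operable cataract eye -> denominator only
    participant("f10", "c2", r_lens = "NO_VIEW", r_pva = NA, r_bcva = NA,
                r_cause = NA, l_lens = "PHAKIC_CATARACT",
                l_pva = "LT_6_60_GE_3_60", l_bcva = "LT_6_60_GE_3_60",
                l_cause = "CATARACT"),
    # 11: bilateral pseudophakia, poor outcomes in both eyes
    participant("f11", "c2", r_lens = "PSEUDOPHAKIA",
                l_lens = "PSEUDOPHAKIA",
                r_pva = "LT_6_18_GE_6_60", l_pva = "LT_6_60_GE_3_60"),
    # 12: unilateral aphakia with good outcome, unimpaired fellow eye
    participant("f12", "c2", r_lens = "APHAKIA",
                r_pva = "LT_6_12_GE_6_18",
                l_lens = "PHAKIC_CATARACT", l_pva = "GE_6_12",
                l_bcva = "GE_6_12", l_cause = "NONE")
  )
}

test_that("eye-level predicates follow the lens and acuity definitions", {
  expect_true(eye_operated("PSEUDOPHAKIA"))
  expect_true(eye_operated("APHAKIA"))
  expect_false(eye_operated("PHAKIC_CATARACT"))
  expect_false(eye_operated("NO_VIEW"))
  expect_false(eye_operated(NA))

  expect_true(eye_operable("PHAKIC_CATARACT", "LT_6_18_GE_6_60",
                           "CATARACT", "6/18"))
  # better than every cut: never operable
  for (cut in c("3/60", "6/60", "6/18", "6/12")) {
    expect_false(eye_operable("PHAKIC_CATARACT", "GE_6_12", "CATARACT", cut))
  }
  expect_false(eye_operable("PHAKIC_CLEAR", "LT_3_60", "OTHER", "6/18"))
  expect_false(eye_operable("PHAKIC_CATARACT", "LT_3_60", "OTHER", "6/18"))
  expect_true(eye_operable("PHAKIC_CATARACT", "LT_3_60", "OTHER", "6/18",
                           require_cataract_cause = FALSE))
})

test_that("hand-classified fixture matches the frozen tally (all-operated)", {
  cl <- classify_participants(fixture12(), indicator_config())
  expect_equal(cl$participant_id[cl$in_denom],
               paste0("f", sprintf("%02d", c(1, 3, 4, 7, 9, 10, 11, 12))))
  expect_equal(cl$participant_id[cl$in_csc_num],
               paste0("f", sprintf("%02d", c(1, 4, 7, 9, 11, 12))))
  expect_equal(cl$participant_id[cl$in_ecsc_num], c("f01", "f07", "f12"))
  expect_equal(cl$participant_id[cl$unclassifiable], "f08")
  expect_equal(cl$participant_id[cl$ecsc_excluded], "f09")
  expect_equal(cl$postop_pva[cl$participant_id == "f01"], "GE_6_12")
  expect_equal(cl$postop_pva[cl$participant_id == "f11"], "LT_6_18_GE_6_60")
  expect_equal(cl$operated[match(c("f01", "f04", "f02"),
                                 cl$participant_id)],
               c("bilateral", "unilateral", "none"))
})

test_that("fellow-impaired rule drops unilateral cases with healthy fellow eyes", {
  cfg <- indicator_config(unilateral_rule = "fellow_impaired_only")
  cl <- classify_participants(fixture12(), cfg)
  expect_equal(cl$participant_id[cl$in_csc_num], c("f01", "f07", "f11"))
  expect_equal(cl$participant_id[cl$in_ecsc_num], c("f01", "f07"))
  expect_equal(cl$participant_id[cl$in_denom],
               c("f01", "f03", "f07", "f10", "f11"))
  # unilateral with an ungradable fellow eye is excluded and tallied
  p <- participant("x1", "c1", r_lens = "PSEUDOPHAKIA", r_pva = "GE_6_12",
                   l_lens = "NO_VIEW", l_pva = NA, l_bcva = NA,
                   l_cause = NA)
  clx <- classify_participants(p, cfg)
  expect_false(clx$in_csc_num)
  expect_true(clx$csc_excluded)
})

test_that("stratum and cluster tallies are additive and order-invariant", {
  survey <- fixture12()
  cfg <- indicator_config()
  by_stratum <- survey_counts(survey, cfg, by = "stratum")
  by_cluster <- survey_counts(survey, cfg, by = "cluster")
  total <- survey_counts(survey, cfg, by = "total")
  for (col in c("examined", "denom", "csc_num", "ecsc_num")) {
    expect_equal(sum(by_stratum[[col]]), total[[col]])
    expect_equal(sum(by_cluster[[col]]), total[[col]])
  }
  expect_equal(total$csc_num, 6)
  expect_equal(total$denom, 8)
  expect_equal(total$ecsc_num, 3)
  shuffled <- survey[sample(nrow(survey)), ]
  expect_equal(survey_counts(shuffled, cfg, by = "total"), total)
})

test_that("subset chain eCSC -> CSC -> denominator holds on random input", {
  survey <- random_participants(400, seed = 42)
  for (rule in c("all_operated", "fellow_impaired_only")) {
    for (cfg in all_indicator_configs(rule)) {
      cl <- classify_participants(survey, cfg)
      expect_true(all(cl$in_csc_num[cl$in_ecsc_num]), info = config_label(cfg))
      expect_true(all(cl$in_denom[cl$in_csc_num]), info = config_label(cfg))
      expect_true(all(!cl$in_csc_num[cl$operated %in% "none"]))
      expect_true(all(!cl$in_denom[cl$unclassifiable]))
    }
  }
})

test_that("classification is pure and monotone in both thresholds", {
  survey <- random_participants(400, seed = 7)
  c1 <- classify_participants(survey, indicator_config())
  c2 <- classify_participants(survey, indicator_config())
  expect_identical(c1, c2)

  # tightening the outcome cut never adds an eCSC member
  e18 <- classify_participants(survey, indicator_config("6/18", "6/18"))
  e12 <- classify_participants(survey, indicator_config("6/18", "6/12"))
  expect_true(all(e18$in_ecsc_num[e12$in_ecsc_num]))

  # relaxing the surgical cut never removes a denominator member
  cuts <- c("3/60", "6/60", "6/18", "6/12")
  denoms <- lapply(cuts, function(ct) {
    classify_participants(survey, indicator_config(ct, "6/18"))$in_denom
  })
  for (i in seq_len(length(cuts) - 1)) {
    expect_true(all(denoms[[i + 1]][denoms[[i]]]),
                info = paste(cuts[i], "->", cuts[i + 1]))
  }
})
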