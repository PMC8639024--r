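test_that("ICD code matching covers the stated ranges, dialects, and the Rett exclusion", {
  yes <- c("299.00", "299.99", "299.0", "299", "299.80", "F84.0", "F84.5",
           "F84.9", "F840", "f84.0", " F84.0 ")
  no <- c("F84.2", "F84.20", "F842", "F83", "F85.0", "300.00", "298.9",
          "315.39")
  expect_true(all(is_asd_indicator_code(yes)))
  expect_false(any(is_asd_indicator_code(no)))
  expect_warning(res1 <- is_asd_indicator_code("autism"), "unparseable")
  expect_warning(res2 <- is_asd_indicator_code(c("", NA)), "empty or missing")
  expect_false(any(res1, res2))
  expect_equal(is_asd_indicator_code(character(0)), logical(0))
})

test_that("merging unions indicators and restricts inaccessible records to trigger codes", {
  health <- sr("c1", icd = icd_tbl("F84.0"))
  edu <- sr("c1", source_type = "education", sped = sped_tbl())
  m <- merge_child_records(list(health, edu))
  expect_equal(nrow(m$icd_codes), 1)
  expect_equal(nrow(m$sped), 1)

  # inaccessible record: ICD kept, evaluation content dropped
  inacc <- sr("c2", accessible = FALSE, icd = icd_tbl("F84.0"),
              evaluations = eval_tbl(50, "asd-diagnosis"))
  m2 <- merge_child_records(list(inacc))
  st2 <- classify_case(m2)
  expect_true(st2$has_icd)
  expect_false(st2$has_dx_statement)
  expect_equal(st2$region, "icd-only")

  expect_error(merge_child_records(list()),
               class = "asdsurv_consistency_error")
  expect_error(merge_child_records(list(sr("a"), sr("b"))),
               class = "asdsurv_consistency_error")
})

test_that("case definition applies the three indicator clauses and eligibility gates", {
  # Rett-only child is never a case
  rett <- classify_case(merge_child_records(list(sr("c1",
                                                    icd = icd_tbl("F84.2")))))
  expect_false(rett$is_case)
  expect_equal(rett$region, "none")

  # special-education eligibility alone suffices
  sped_only <- classify_case(merge_child_records(list(
    sr("c2", source_type = "education", sped = sped_tbl()))))
  expect_true(sped_only$is_case)
  expect_equal(sped_only$region, "sped-only")

  # all three indicators but residency fails
  full <- merge_child_records(list(
    sr("c3", icd = icd_tbl("F84.0"), sped = sped_tbl(),
       evaluations = eval_tbl(48, "asd-diagnosis"))))
  expect_false(classify_case(full, resident_in_year = FALSE)$is_case)
  expect_false(classify_case(full, birth_year = 2009)$is_case)
  expect_equal(classify_case(full)$region, "all-three")

  # unqualified diagnostic statement does not count
  unq <- classify_case(merge_child_records(list(
    sr("c4", evaluations = eval_tbl(48, "asd-diagnosis",
                                    qualified = FALSE)))))
  expect_false(unq$has_dx_statement)
  expect_false(unq$is_case)

  # monotonicity: adding an indicator never removes case status
  base <- sr("c5", icd = icd_tbl("F84.0"))
  with_more <- sr("c5", source_type = "education", sped = sped_tbl())
  s_base <- classify_case(merge_child_records(list(base)))
  s_more <- classify_case(merge_child_records(list(base, with_more)))
  expect_true(s_base$is_case)
  expect_true(s_more$is_case)
})

test_that("diagnosis history orders suspected/ruled-out/diagnosed conclusions", {
  # ruled out then diagnosed: not more recent
  m1 <- merge_child_records(list(sr("c1", evaluations = eval_tbl(
    c(30, 45), c("asd-ruled-out", "asd-diagnosis")))))
  h1 <- diagnosis_history(m1)
  expect_true(h1$ruled_out_ever)
  expect_false(h1$ruled_out_more_recent)
  expect_equal(h1$earliest_dx_age_months, 45)

  # diagnosed then ruled out: more recent
  m2 <- merge_child_records(list(sr("c2", evaluations = eval_tbl(
    c(40, 70), c("asd-diagnosis", "asd-ruled-out")))))
  expect_true(diagnosis_history(m2)$ruled_out_more_recent)

  # equal months are not ordered
  m3 <- merge_child_records(list(sr("c3", evaluations = eval_tbl(
    c(40, 40), c("asd-diagnosis", "asd-ruled-out")))))
  expect_false(diagnosis_history(m3)$ruled_out_more_recent)

  # reported prior diagnosis sets the earliest age
  m4 <- merge_child_records(list(sr("c4", evaluations = eval_tbl(
    50, "other", reported = 38))))
  h4 <- diagnosis_history(m4)
  expect_equal(h4$earliest_dx_age_months, 38)
  st4 <- classify_case(m4)
  expect_true(st4$has_dx_statement)

  # suspected flag
  m5 <- merge_child_records(list(sr("c5", evaluations = eval_tbl(
    c(30, 45), c("asd-suspected", "asd-diagnosis")))))
  expect_true(diagnosis_history(m5)$suspected_ever)
})

test_that("earliest evaluation age uses the 36-month inclusive boundary", {
  m <- merge_child_records(list(sr("c1", evaluations = eval_tbl(
    c(36, 48), c("other", "asd-diagnosis")))))
  ev <- earliest_evaluation_age(m)
  expect_equal(ev$age_months, 36)
  expect_true(ev$by_36_months)

  m37 <- merge_child_records(list(sr("c2",
                                     evaluations = eval_tbl(37, "other"))))
  expect_false(earliest_evaluation_age(m37)$by_36_months)

  none <- merge_child_records(list(sr("c3", icd = icd_tbl("F84.0"))))
  expect_true(is.na(earliest_evaluation_age(none)$age_months))

  # a reported prior diagnosis age counts as evaluation information
  rep <- merge_child_records(list(sr("c4", evaluations = eval_tbl(
    50, "other", reported = 30))))
  expect_equal(earliest_evaluation_age(rep)$age_months, 30)
})

test_that("cognitive classification takes the most recent entry with the tie rules", {
  m <- merge_child_records(list(sr("c1", cognitive = cog_tbl(
    c(60, 80), c("test-score", "test-score"), scores = c(65, 90)))))
  expect_equal(classify_cognitive(m), ">85")

  expect_equal(classify_cognitive(merge_child_records(list(sr("c2",
    cognitive = cog_tbl(60, "test-score", scores = 70))))), "<=70")
  expect_equal(classify_cognitive(merge_child_records(list(sr("c3",
    cognitive = cog_tbl(60, "test-score", scores = 85))))), "71-85")
  expect_equal(classify_cognitive(merge_child_records(list(sr("c4",
    cognitive = cog_tbl(60, "examiner-statement", bands = "71-85"))))),
    "71-85")

  # equal-age tie: test score beats examiner statement
  tie <- merge_child_records(list(sr("c5", cognitive = cog_tbl(
    c(70, 70), c("examiner-statement", "test-score"),
    scores = c(NA, 95), bands = c("<=70", NA)))))
  expect_equal(classify_cognitive(tie), ">85")

  expect_true(is.na(classify_cognitive(merge_child_records(list(
    sr("c6", icd = icd_tbl("F84.0")))))))
})

test_that("vectorized ascertainment agrees with per-child brute force on random populations", {
  cfgs <- list(
    generator_config(site_config("s1", 150, record_accessible_fraction = 0.6,
                                 true_prevalence = 0.3,
                                 false_trigger_rate = 0.1)),
    generator_config(site_config("s2", 150, has_education_source = FALSE,
                                 true_prevalence = 0.25)))
  for (cfg in cfgs) {
    pop <- generate_population(cfg, seed = 11)
    rs <- quiet_records(pop$children, cfg, seed = 12)
    st <- ascertain_cases(pop$children, rs)
    for (cid in st$child_id) {
      recs <- child_records(rs, cid)
      bf <- brute_force_case(recs)
      expect_equal(st$is_case[st$child_id == cid], bf)
      merged <- merge_child_records(recs)
      one <- classify_case(merged)
      for (col in c("has_dx_statement", "has_sped", "has_icd", "is_case",
                    "region", "suspected_ever", "ruled_out_ever",
                    "ruled_out_more_recent")) {
        expect_equal(st[[col]][st$child_id == cid], one[[col]])
      }
      expect_equal(st$earliest_dx_age_months[st$child_id == cid],
                   as.integer(one$earliest_dx_age_months))
      expect_equal(st$cognitive_band[st$child_id == cid],
                   one$cognitive_band)
    }
  }
})

test_that("identification regions partition the cases and shares close", {
  cfg <- generator_config(site_config("s1", 4000, true_prevalence = 0.1,
                                      record_accessible_fraction = 1))
  pop <- generate_population(cfg, seed = 5)
  rs <- quiet_records(pop$children, cfg, seed = 6)
  st <- ascertain_cases(pop$children, rs)
  cases <- st[st$is_case, ]
  reg <- identification_regions(cases)
  expect_equal(sum(reg$counts$n), nrow(cases))
  expect_equal(unname(reg$shares["any_dx"] + reg$shares["sped_no_dx"] +
                        reg$shares["icd_only"]), 100)
  expect_error(identification_regions(st),
               class = "asdsurv_validation_error")
})
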