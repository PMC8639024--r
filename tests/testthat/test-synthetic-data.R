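test_that("configuration validation names the offending field", {
  expect_error(site_config("s", 0), "n_children",
               class = "asdsurv_config_error")
  expect_error(site_config("s", 10, pct_male = 1.5), "pct_male",
               class = "asdsurv_config_error")
  bad_mix <- network_identification_mixture()
  bad_mix[1] <- bad_mix[1] + 0.01
  expect_error(site_config("s", 10, identification_mixture = bad_mix),
               "identification_mixture", class = "asdsurv_config_error")
  expect_error(site_config("s", 10, race_mix = c(a = 1)), "race_mix",
               class = "asdsurv_config_error")
  expect_error(
    generator_config(list(site_config("a", 10), site_config("a", 10))),
    "unique", class = "asdsurv_config_error")
  expect_error(generator_config(list()), class = "asdsurv_config_error")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(site_config("s1", 1000, true_prevalence = 0.05))
  p1 <- generate_population(cfg, seed = 7)
  p2 <- generate_population(cfg, seed = 7)
  expect_identical(p1, p2)
  r1 <- quiet_records(p1$children, cfg, seed = 7)
  r2 <- quiet_records(p2$children, cfg, seed = 7)
  expect_identical(r1, r2)
  p3 <- generate_population(cfg, seed = 8)
  expect_false(identical(p1$children$is_true_case, p3$children$is_true_case))
})

test_that("population structure matches the configuration", {
  cfg <- generator_config(site_config("s1", 5000, true_prevalence = 0,
                                      missing_tract_fraction = 0.1))
  pop <- generate_population(cfg, seed = 3)
  expect_equal(sum(pop$children$is_true_case), 0)
  expect_false(anyDuplicated(pop$children$child_id) > 0)

  # denominator conservation: cells equal generated child counts
  expect_equal(network_total(pop$denominators), 5000)
  expect_equal(site_totals(pop$denominators)$n, 5000)
  counted <- dplyr::count(pop$children, site, sex, race_ethnicity)
  merged <- merge(counted, as.data.frame(pop$denominators),
                  by = c("site", "sex", "race_ethnicity"))
  expect_equal(merged$n.x, merged$n.y)

  # tract conservation and the age-8 estimate rule
  expect_equal(sum(pop$tracts$n_age_5_9), 5 * 5000)
  expect_equal(pop$tracts$est_age_8, pop$tracts$n_age_5_9 / 5)

  # missing-tract fraction near configuration
  expect_equal(mean(is.na(pop$children$census_tract)), 0.1,
               tolerance = 0.25)
})

test_that("true-case sampling recovers the configured prevalence and sex ratio", {
  n <- 220281
  p_true <- 0.023
  cfg <- generator_config(site_config("s1", n, true_prevalence = p_true))
  reps <- 30
  fractions <- vapply(seq_len(reps), function(i) {
    mean(generate_population(cfg, seed = 100 + i)$children$is_true_case)
  }, numeric(1))
  mc_se <- sqrt(p_true * (1 - p_true) / n) / sqrt(reps)
  expect_lt(abs(mean(fractions) - p_true), 3 * mc_se)

  # sex-specific rates reflect the configured 4.2 rate ratio
  pop <- generate_population(cfg, seed = 1)
  ch <- pop$children
  rate_m <- mean(ch$is_true_case[ch$sex == "male"])
  rate_f <- mean(ch$is_true_case[ch$sex == "female"])
  expect_equal(rate_m / rate_f, 4.2, tolerance = 0.25)
})

test_that("records realize the sampled identification combinations", {
  cfg <- generator_config(site_config("s1", 3000, true_prevalence = 0.2,
                                      record_accessible_fraction = 1,
                                      false_trigger_rate = 0.05))
  pop <- generate_population(cfg, seed = 21)
  rs <- quiet_records(pop$children, cfg, seed = 22)
  st <- ascertain_cases(pop$children, rs)

  # ICD-only cases carry no diagnostic statement or eligibility
  icd_only <- st[st$is_case & st$region == "icd-only", ]
  expect_gt(nrow(icd_only), 0)
  expect_false(any(icd_only$has_dx_statement))
  expect_false(any(icd_only$has_sped))

  # false triggers: non-case children whose only code is F84.2
  triggers <- rs$icd[rs$icd$code == "F84.2", ]
  expect_gt(nrow(triggers), 0)
  trig_children <- rs$records$child_id[match(triggers$record_id,
                                             rs$records$record_id)]
  expect_false(any(pop$children$is_true_case[
    pop$children$child_id %in% trig_children]))
  expect_false(any(st$is_case[st$child_id %in% trig_children]))

  # with full accessibility, every dx-combination case has a statement
  expect_equal(sum(st$is_case), sum(pop$children$is_true_case))
})

test_that("mixture marginal recovery over replicates", {
  mix <- network_identification_mixture()
  cfg <- generator_config(site_config("s1", 1500, true_prevalence = 0.15,
                                      record_accessible_fraction = 1))
  reps <- 100
  counts <- setNames(numeric(7), names(mix))
  total <- 0
  for (i in seq_len(reps)) {
    pop <- generate_population(cfg, seed = 300 + i)
    rs <- quiet_records(pop$children, cfg, seed = 600 + i)
    st <- ascertain_cases(pop$children, rs)
    tab <- table(factor(st$region[st$is_case], levels = names(mix)))
    counts <- counts + as.numeric(tab)
    total <- total + sum(tab)
  }
  for (nm in names(mix)) {
    se <- sqrt(mix[[nm]] * (1 - mix[[nm]]) / total)
    expect_lt(abs(counts[[nm]] / total - mix[[nm]]), 3 * se + 1e-12)
  }
})

test_that("education-source masking hides special-education indicators", {
  mk <- function(educ) generator_config(site_config(
    "s1", 3000, true_prevalence = 0.1, has_education_source = educ,
    record_accessible_fraction = 1))
  pop_full <- generate_population(mk(TRUE), seed = 9)
  pop_blind <- generate_population(mk(FALSE), seed = 9)
  expect_equal(pop_full$children$is_true_case, pop_blind$children$is_true_case)
  rs_blind <- quiet_records(pop_blind$children, mk(FALSE), seed = 10)
  expect_equal(nrow(rs_blind$sped), 0)
  expect_false(any(rs_blind$records$source_type == "education"))
  st_blind <- ascertain_cases(pop_blind$children, rs_blind)
  expect_false(any(st_blind$has_sped))

  rs_full <- quiet_records(pop_full$children, mk(TRUE), seed = 10)
  st_full <- ascertain_cases(pop_full$children, rs_full)
  expect_gt(sum(st_full$is_case), sum(st_blind$is_case))
})

test_that("presets carry the documented source-access profile", {
  mo <- scenario_preset("missouri")
  expect_false(mo$sites$missouri$has_education_source)
  md <- scenario_preset("maryland")
  expect_equal(md$sites$maryland$record_accessible_fraction, 0.314)
  expect_error(scenario_preset("unknown-site"),
               class = "asdsurv_lookup_error")
  net <- scenario_preset("network")
  expect_equal(length(net$sites), 11)
  expect_equal(sum(vapply(net$sites, `[[`, numeric(1), "n_children")),
               220281)
  # every preset mixture reproduces its marginal shares
  tab <- asdsurv:::preset_table()
  for (i in seq_len(nrow(tab))) {
    mix <- scenario_preset(tab$key[i])$sites[[1]]$identification_mixture
    dx <- sum(mix[c("dx-only", "dx+sped", "dx+icd", "all-three")])
    icd <- sum(mix[c("icd-only", "dx+icd", "sped+icd", "all-three")])
    expect_equal(dx, tab$m_dx[i], tolerance = 1e-6)
    expect_equal(icd, tab$m_icd[i], tolerance = 1e-6)
  }
})

test_that("configs round-trip through YAML and JSON", {
  cfg <- generator_config(list(site_config("a", 100),
                               site_config("b", 200,
                                           has_education_source = FALSE)),
                          global_seed = 5L)
  for (ext in c("yaml", "json")) {
    path <- file.path(withr::local_tempdir(), paste0("cfg.", ext))
    write_generator_config(cfg, path)
    back <- read_generator_config(path)
    expect_equal(back$sites$a$race_mix, cfg$sites$a$race_mix)
    expect_equal(back$sites$b$has_education_source, FALSE)
    expect_equal(back$global_seed, 5L)
    p1 <- generate_population(cfg, seed = 2)
    p2 <- generate_population(back, seed = 2)
    expect_identical(p1$children, p2$children)
  }
})

test_that("record sets round-trip through CSV and export to nested JSON", {
  cfg <- generator_config(site_config("s1", 400, true_prevalence = 0.1))
  pop <- generate_population(cfg, seed = 31)
  rs <- quiet_records(pop$children, cfg, seed = 32)
  dir <- withr::local_tempdir()
  write_record_set(rs, dir)
  back <- read_record_set(dir)
  for (nm in c("records", "icd", "sped", "evaluations", "cognitive")) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(rs[[nm]]))
  }
  jpath <- file.path(dir, "records.json")
  write_records_json(rs, jpath)
  parsed <- jsonlite::read_json(jpath)
  expect_equal(length(parsed), length(unique(rs$records$child_id)))
})
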